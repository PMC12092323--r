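# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force maximum one-to-one matching size: enumerate all injective
# assignments of predictions to ground-truth dots within tolerance.
brute_force_tp <- function(pred, gt, tolerance) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  dmat <- sqrt(outer(pred$x, gt$x, `-`)^2 + outer(pred$y, gt$y, `-`)^2)
  ok <- dmat <= tolerance
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, used, count)        # leave prediction i unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# Flood-fill connected-component count (8-connectivity), independent of the
# watershed path under test.
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- 0L
  sizes <- integer(0)
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      comps <- comps + 1L
      size <- 0L
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  list(count = comps, sizes = sizes)
}

# Random set of disjoint square/rectangular blobs with a gap guarantee;
# returns the mask and the number of blobs placed.
random_disjoint_blob_mask <- function(H = 48, W = 48, max_blobs = 6) {
  mask <- matrix(FALSE, H, W)
  occupied <- matrix(FALSE, H, W)   # blobs plus a 2-pixel moat
  placed <- 0L
  for (i in seq_len(max_blobs)) {
    h <- sample(2:5, 1); w <- sample(2:5, 1)
    for (try in 1:50) {
      r <- sample(H - h + 1, 1); c <- sample(W - w + 1, 1)
      rr <- max(1, r - 2):min(H, r + h + 1)
      cc <- max(1, c - 2):min(W, c + w + 1)
      if (!any(occupied[rr, cc])) {
        mask[r:(r + h - 1), c:(c + w - 1)] <- TRUE
        occupied[rr, cc] <- TRUE
        placed <- placed + 1L
        break
      }
    }
  }
  list(mask = mask, n = placed)
}

# Direct (naive) 2-D convolution with zero padding, for blur oracles.
naive_convolve <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  k <- nrow(kernel); r <- (k - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + img[ii, jj] * kernel[di + r + 1, dj + r + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Small helper: build a training sample list from seeded synthetic patches.
make_synthetic_samples <- function(seeds, shape) {
  lapply(seeds, function(s) {
    p <- generate_patch(s, shape = shape)
    list(image = p$image, dots = p$dots[, c("x", "y")])
  })
}
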