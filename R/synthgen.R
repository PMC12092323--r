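# Synthetic patch generation: haematoxylin-like textured backgrounds carrying
# artificial DAB dots with perfectly known coordinates. Dots are built as
# subtractive BGR masks: a single opposite-colour centre pixel blurred with a
# circular Gaussian kernel, rescaled so the centre regains its pre-blur
# value, optionally combined with a dark-centred secondary mask, then
# perturbed (cardinal stretch, anisotropic scale, multiplicative noise,
# rotation).
#
# Conventions: channel order BGR (the printed colour triples are BGR);
# coordinates 0-based with x = column, y = row; mask values stay floating
# point until they are applied to a patch.

DOT_COLOUR_LIGHT <- c(225, 253, 255)  # light yellow, BGR
DOT_COLOUR_DARK <- c(160, 200, 217)   # dark brown, BGR
SECONDARY_COLOUR <- c(200, 210, 215)  # dark-centred secondary dot, BGR
MIN_SEPARATION <- 3

#' Per-patch artificial dot count
#'
#' `n = round(2^(1 + 5r))`, an exponential scale from 2 to 64 reflecting
#' that patches tend to hold either few dots or many. Rounding is
#' half-up.
#'
#' @param r uniform random draw in `[0,1]`.
#' @return integer dot count in `[2, 64]`.
#' @export
sample_dot_count <- function(r) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0,1]")
  as.integer(round_half_up(2^(1 + 5 * r)))
}

#' Shared scale offset
#'
#' `r' = 0.4 r^2`: a squared uniform draw added to both axis scale factors,
#' so substantially larger dots are rare but possible.
#'
#' @param r uniform random draw in `[0,1]`.
#' @return scale addend in `[0, 0.4]`.
#' @export
sample_scale_offset <- function(r) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0,1]")
  0.4 * r^2
}

round_half_up <- function(x) floor(x + 0.5)

#' Primary dot colour interpolation
#'
#' Channel-wise linear blend from light yellow `(225, 253, 255)` at `t = 0`
#' to dark brown `(160, 200, 217)` at `t = 1` (BGR), the same interpolant
#' driving all three channels.
#'
#' @param t interpolant in `[0,1]`.
#' @return numeric BGR triple (unquantized).
#' @export
interpolate_primary_colour <- function(t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0,1]")
  (1 - t) * DOT_COLOUR_LIGHT + t * DOT_COLOUR_DARK
}

# Circular Gaussian kernel: sigma = size/4, values zeroed outside the
# inscribed circle, normalized to sum 1.
circular_gaussian_kernel <- function(size) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  sigma <- size / 4
  d <- seq(-r, r)
  g <- exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  g[outer(d^2, d^2, `+`) > r^2] <- 0
  g / sum(g)
}

dot_mask <- function(values, anchor, dot_type) {
  structure(list(values = values, anchor = anchor, dot_type = dot_type),
            class = "dot_mask")
}

# Build a blurred-and-rescaled single-colour mask of the given kernel size.
make_blurred_mask <- function(colour, kernel_size, dot_type) {
  centre_val <- 255 - colour
  k <- circular_gaussian_kernel(kernel_size)
  # blurring a single centre pixel is the kernel itself, scaled per channel;
  # the rescale restores the centre to its pre-blur value
  kc <- k[(kernel_size + 1) / 2, (kernel_size + 1) / 2]
  vals <- array(0, dim = c(kernel_size, kernel_size, 3))
  for (c in 1:3) vals[, , c] <- k / kc * centre_val[c]
  anchor <- c((kernel_size - 1) / 2, (kernel_size - 1) / 2)  # (x, y), 0-based
  dot_mask(vals, anchor, dot_type)
}

#' Primary dot mask
#'
#' The centre pixel is set to the opposite of the dot colour
#' (`255 - value` per channel), blurred with a 9x9 circular Gaussian, then
#' multiplied so the centre regains its pre-blur value. The result is a
#' subtractive mask whose values fade radially.
#'
#' @param colour BGR triple from [interpolate_primary_colour()].
#' @param kernel_size blur kernel size (default 9).
#' @return a `dot_mask` object.
#' @export
make_primary_dot_mask <- function(colour, kernel_size = 9) {
  stopifnot(all(colour >= 0), all(colour <= 255))
  make_blurred_mask(colour, kernel_size, "primary")
}

#' Secondary (dark-centred) dot mask
#'
#' Same construction as the primary mask but with the fixed colour
#' `(200, 210, 215)` and a smaller 5x5 circular kernel, giving a central
#' darkening of at least 40 on every channel.
#'
#' @return a `dot_mask` object.
#' @export
make_secondary_dot_mask <- function() {
  make_blurred_mask(SECONDARY_COLOUR, 5, "secondary")
}

#' Combine primary and secondary masks
#'
#' Adds the secondary mask onto the primary with its centre offset by
#' `(dx, dy)` in `{-1, 0, 1}`, replicating the off-centre yellow tinges of
#' dark dots. The sum is clipped at 255.
#'
#' @param primary,secondary `dot_mask` objects.
#' @param offset integer `c(dx, dy)`, each in -1..1.
#' @return a `dot_mask` of type `"secondary"`.
#' @export
combine_masks <- function(primary, secondary, offset = c(0, 0)) {
  if (any(abs(offset) > 1)) stop("offset components must be in {-1, 0, 1}")
  pv <- primary$values
  sv <- secondary$values
  pa <- primary$anchor
  sa <- secondary$anchor
  sh <- dim(sv)[1:2]
  # top-left of the secondary mask inside the primary canvas (row, col)
  oy <- pa[2] + offset[2] - sa[2]
  ox <- pa[1] + offset[1] - sa[1]
  out <- pv
  for (r in seq_len(sh[1])) {
    rr <- oy + r - 1          # 0-based destination row
    if (rr < 0 || rr >= dim(pv)[1]) next
    for (cc in seq_len(sh[2])) {
      c2 <- ox + cc - 1
      if (c2 < 0 || c2 >= dim(pv)[2]) next
      out[rr + 1, c2 + 1, ] <- pmin(out[rr + 1, c2 + 1, ] + sv[r, cc, ], 255)
    }
  }
  dot_mask(out, pa, "secondary")
}

#' Perturbation parameters for one dot
#'
#' @param cardinal_stretch integer pixels (0-3) each cardinal direction is
#'   stretched by, ordered `(+x, -x, +y, -y)`.
#' @param base_scale_x,base_scale_y axis scale factors.
#' @param shared_offset the shared addend `r'` from
#'   [sample_scale_offset()].
#' @param noise_low,noise_high multiplicative per-pixel noise bounds.
#' @param rotation integer rotation angle in degrees (0-359).
#' @export
perturb_params <- function(cardinal_stretch = c(0, 0, 0, 0),
                           base_scale_x = 0.375, base_scale_y = 0.375,
                           shared_offset = 0,
                           noise_low = 0.975, noise_high = 1.025,
                           rotation = 0L) {
  stopifnot(length(cardinal_stretch) == 4, all(cardinal_stretch >= 0),
            all(cardinal_stretch <= 3),
            base_scale_x > 0, base_scale_y > 0,
            shared_offset >= 0, shared_offset <= 0.4,
            noise_low <= noise_high,
            rotation >= 0, rotation <= 359)
  structure(list(cardinal_stretch = as.integer(cardinal_stretch),
                 base_scale_x = base_scale_x, base_scale_y = base_scale_y,
                 shared_offset = shared_offset,
                 noise_low = noise_low, noise_high = noise_high,
                 rotation = as.integer(rotation)),
            class = "perturb_params")
}

# Resample a mask through an invertible per-axis coordinate mapping.
# map_x / map_y take destination offsets from the anchor and return source
# offsets; bilinear interpolation with zero padding.
resample_mask <- function(values, anchor, half_out, map_x, map_y) {
  H <- dim(values)[1]; W <- dim(values)[2]
  side <- 2 * half_out + 1
  dst <- seq(-half_out, half_out)
  sx <- map_x(dst) + anchor[1]
  sy <- map_y(dst) + anchor[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  getp <- function(plane, yi, xi) {
    # yi rows, xi cols (0-based); outside -> 0
    out <- matrix(0, side, side)
    Yi <- matrix(yi, side, side)
    Xi <- matrix(xi, side, side, byrow = TRUE)
    ok <- Yi >= 0 & Yi < H & Xi >= 0 & Xi < W
    out[ok] <- plane[cbind(Yi[ok] + 1, Xi[ok] + 1)]
    out
  }
  FY <- matrix(fy, side, side)
  FX <- matrix(fx, side, side, byrow = TRUE)
  out <- array(0, dim = c(side, side, 3))
  for (c in 1:3) {
    p <- values[, , c]
    out[, , c] <- getp(p, y0, x0) * (1 - FX) * (1 - FY) +
      getp(p, y0, x0 + 1) * FX * (1 - FY) +
      getp(p, y0 + 1, x0) * (1 - FX) * FY +
      getp(p, y0 + 1, x0 + 1) * FX * FY
  }
  out
}

#' Perturb a dot mask
#'
#' Applies, in order: cardinal stretch (each half-axis resampled to extend
#' its radial length by 0-3 pixels), anisotropic scaling by
#' `(base_scale_x + r', base_scale_y + r')`, multiplicative per-pixel
#' per-channel noise, and rotation by an integer angle about the anchor
#' (bilinear, zero padding). The anchor remains the dot coordinate.
#'
#' @param mask a `dot_mask`.
#' @param params a [perturb_params()].
#' @return a `dot_mask`.
#' @export
perturb_dot <- function(mask, params) {
  stopifnot(inherits(mask, "dot_mask"), inherits(params, "perturb_params"))
  v <- mask$values
  a <- mask$anchor
  R <- max(a[1], a[2], dim(v)[1] - 1 - a[2], dim(v)[2] - 1 - a[1])
  st <- params$cardinal_stretch  # (+x, -x, +y, -y)
  # 1) cardinal stretch: per-direction radial extension by resampling
  half1 <- R + max(st)
  stretch_map <- function(plus, minus) {
    function(d) {
      s <- d
      pos <- d > 0; neg <- d < 0
      s[pos] <- d[pos] * R / (R + plus)
      s[neg] <- d[neg] * R / (R + minus)
      s
    }
  }
  v <- resample_mask(v, a, half1,
                     stretch_map(st[1], st[2]),
                     stretch_map(st[3], st[4]))
  a <- c(half1, half1)
  # clamp the support so each stretched half-axis ends exactly at R + s
  dst <- seq(-half1, half1)
  xbad <- dst > R + st[1] | dst < -(R + st[2])
  ybad <- dst > R + st[3] | dst < -(R + st[4])
  v[ybad, , ] <- 0
  v[, xbad, ] <- 0
  # 2) anisotropic scale
  sx <- params$base_scale_x + params$shared_offset
  sy <- params$base_scale_y + params$shared_offset
  half2 <- max(ceiling(half1 * max(sx, sy, 1)), 2)
  v <- resample_mask(v, a, half2,
                     function(d) d / sx,
                     function(d) d / sy)
  a <- c(half2, half2)
  # 3) multiplicative noise, per pixel and per channel
  if (params$noise_high > params$noise_low) {
    noise <- array(stats::runif(length(v), params$noise_low, params$noise_high),
                   dim = dim(v))
    v <- v * noise
  } else if (params$noise_low != 1) {
    v <- v * params$noise_low
  }
  # 4) rotation about the anchor
  if (params$rotation != 0) {
    th <- params$rotation * pi / 180
    side <- dim(v)[1]
    vr <- array(0, dim = dim(v))
    half <- a[1]
    # reuse the resampler with a joint rotation: build full 2-D mapping
    dst <- seq(-half, half)
    XX <- matrix(dst, side, side, byrow = TRUE)
    YY <- matrix(dst, side, side)
    sxr <- cos(th) * XX + sin(th) * YY + a[1]
    syr <- -sin(th) * XX + cos(th) * YY + a[2]
    x0 <- floor(sxr); y0 <- floor(syr)
    fx <- sxr - x0; fy <- syr - y0
    getp <- function(plane, yi, xi) {
      out <- matrix(0, side, side)
      ok <- yi >= 0 & yi < side & xi >= 0 & xi < side
      out[ok] <- plane[cbind(yi[ok] + 1, xi[ok] + 1)]
      out
    }
    for (c in 1:3) {
      p <- v[, , c]
      vr[, , c] <- getp(p, y0, x0) * (1 - fx) * (1 - fy) +
        getp(p, y0, x0 + 1) * fx * (1 - fy) +
        getp(p, y0 + 1, x0) * (1 - fx) * fy +
        getp(p, y0 + 1, x0 + 1) * fx * fy
    }
    v <- vr
  }
  v <- pmin(pmax(v, 0), 255)
  dot_mask(v, a, mask$dot_type)
}

# Trim zero borders, keeping the anchor inside; used to canonicalize masks.
trim_mask <- function(mask, tol = 1e-9) {
  v <- mask$values
  nz <- apply(v, c(1, 2), max) > tol
  if (!any(nz)) {
    return(dot_mask(array(0, dim = c(1, 1, 3)), c(0, 0), mask$dot_type))
  }
  rows <- range(which(rowSums(nz) > 0))
  cols <- range(which(colSums(nz) > 0))
  rows[1] <- min(rows[1], mask$anchor[2] + 1)
  rows[2] <- max(rows[2], mask$anchor[2] + 1)
  cols[1] <- min(cols[1], mask$anchor[1] + 1)
  cols[2] <- max(cols[2], mask$anchor[1] + 1)
  dot_mask(v[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
           c(mask$anchor[1] - (cols[1] - 1), mask$anchor[2] - (rows[1] - 1)),
           mask$dot_type)
}

#' Plan the dots of one synthetic patch
#'
#' Draws the per-patch controls: the dot count (exponential scale 2-64), a
#' continuous colour window of width 0.20 on the yellow-to-brown axis
#' (dot characteristics within a patch tend to be similar), whether the
#' patch carries dark-centred secondary dots (probability 0.25), and if so
#' the per-dot secondary probability (uniform on 0-0.5).
#'
#' @param seed optional integer seed.
#' @return object of class `patch_plan`.
#' @export
plan_patch <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample_dot_count(stats::runif(1))
  win_start <- stats::runif(1, 0, 0.8)
  has_secondary <- stats::runif(1) < 0.25
  secondary_prob <- if (has_secondary) stats::runif(1, 0, 0.5) else 0
  structure(list(n = n,
                 colour_window = c(win_start, win_start + 0.2),
                 has_secondary = has_secondary,
                 secondary_prob = secondary_prob,
                 min_separation = MIN_SEPARATION),
            class = "patch_plan")
}

#' Place dot coordinates with minimum separation
#'
#' Draws integer coordinates uniformly over the patch, redrawing until each
#' is at least 3 pixels (Euclidean) from every other existing or already
#' placed dot. A bounded retry budget guards against overcrowded patches.
#'
#' @param n number of dots to place.
#' @param existing data frame of pre-existing `x`, `y` coordinates (may be
#'   empty or `NULL`).
#' @param shape `c(H, W)`.
#' @param min_separation minimum pairwise Euclidean distance.
#' @param retry_budget redraw attempts allowed per dot.
#' @return data frame with 0-based integer columns `x`, `y`.
#' @export
place_dots <- function(n, existing = NULL, shape, min_separation = MIN_SEPARATION,
                       retry_budget = 1000) {
  H <- shape[1]; W <- shape[2]
  xs <- if (is.null(existing)) numeric(0) else existing$x
  ys <- if (is.null(existing)) numeric(0) else existing$y
  out_x <- integer(0); out_y <- integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retry_budget)) {
      x <- sample.int(W, 1) - 1L
      y <- sample.int(H, 1) - 1L
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= min_separation^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
        out_x <- c(out_x, x); out_y <- c(out_y, y)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place dot ", i, " of ", n, " within the retry budget of ",
           retry_budget, " attempts; patch too crowded")
    }
  }
  data.frame(x = out_x, y = out_y)
}

#' Generate a haematoxylin-like background
#'
#' Produces a bluish-grey textured image: a pale base tint with smooth
#' low-frequency variation plus darker elliptical nucleus-like regions.
#' Channel minima are floored above the darkest dot-centre values so the
#' artificial dots remain the darkest structures on the patch.
#'
#' @param shape `c(H, W)`.
#' @param seed optional integer seed.
#' @return HxWx3 8-bit (0-255) BGR array.
#' @export
generate_background <- function(shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]
  stopifnot(H > 0, W > 0)
  base_bgr <- c(246, 240, 236)       # pale bluish-grey (B > G > R)
  floor_bgr <- c(170, 206, 221)      # brighter than the darkest dot centre
  # smooth low-frequency field from a few random cosines
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  field <- matrix(0, H, W)
  for (k in 1:4) {
    fx <- stats::runif(1, 0.2, 1.5) / max(H, W)
    fy <- stats::runif(1, 0.2, 1.5) / max(H, W)
    ph <- stats::runif(2, 0, 2 * pi)
    field <- field + stats::runif(1, 0.3, 1) *
      cos(2 * pi * (fx * xx + ph[1])) * cos(2 * pi * (fy * yy + ph[2]))
  }
  field <- field / max(abs(field))
  img <- array(0, dim = c(H, W, 3))
  for (c in 1:3) img[, , c] <- base_bgr[c] + 6 * field
  # darker elliptical nucleus-like regions with a bluish-purple cast
  n_nuc <- max(1L, round(H * W / 2500))
  nuc_depth_bgr <- c(28, 34, 48)     # haematoxylin darkens red most, blue least
  for (i in seq_len(n_nuc)) {
    cx <- stats::runif(1, 0, W - 1)
    cy <- stats::runif(1, 0, H - 1)
    ax <- stats::runif(1, 5, 14)
    ay <- stats::runif(1, 5, 14)
    th <- stats::runif(1, 0, pi)
    depth <- stats::runif(1, 0.4, 1)
    dx <- (xx - 1 - cx); dy <- (yy - 1 - cy)
    u <- (cos(th) * dx + sin(th) * dy) / ax
    v <- (-sin(th) * dx + cos(th) * dy) / ay
    d2 <- u^2 + v^2
    soft <- pmax(0, 1 - d2)          # quadratic falloff to the ellipse edge
    for (c in 1:3) img[, , c] <- img[, , c] - depth * nuc_depth_bgr[c] * soft
  }
  # fine pixel noise
  img <- img + array(stats::rnorm(H * W * 3, 0, 1.5), dim = dim(img))
  for (c in 1:3) img[, , c] <- pmin(pmax(img[, , c], floor_bgr[c]), 255)
  round_half_up(img)
}

#' Apply subtractive dot masks to an image
#'
#' Each mask is subtracted from the image around its coordinate (mask
#' anchor on the dot position), the result clipped to `[0, 255]` and
#' quantized. Coordinates and dot types are recorded exactly.
#'
#' @param image HxWx3 8-bit BGR array.
#' @param masks_with_coords list of `list(mask = dot_mask, x =, y =)`.
#' @param seed seed recorded in the output (bookkeeping only).
#' @return object of class `synthetic_patch`: `image`, `dots`
#'   (data frame `x`, `y`, `type`), `seed`.
#' @export
apply_dots <- function(image, masks_with_coords, seed = NA_integer_) {
  H <- dim(image)[1]; W <- dim(image)[2]
  img <- image * 1.0
  xs <- integer(0); ys <- integer(0); types <- character(0)
  for (mc in masks_with_coords) {
    m <- mc$mask
    x <- mc$x; y <- mc$y
    if (x < 0 || x >= W || y < 0 || y >= H) stop("dot anchor out of bounds")
    mh <- dim(m$values)[1]; mw <- dim(m$values)[2]
    top <- y - m$anchor[2]; left <- x - m$anchor[1]
    r1 <- max(0, top); r2 <- min(H - 1, top + mh - 1)
    c1 <- max(0, left); c2 <- min(W - 1, left + mw - 1)
    if (r1 <= r2 && c1 <= c2) {
      mr <- (r1 - top + 1):(r2 - top + 1)
      mcid <- (c1 - left + 1):(c2 - left + 1)
      img[(r1 + 1):(r2 + 1), (c1 + 1):(c2 + 1), ] <-
        img[(r1 + 1):(r2 + 1), (c1 + 1):(c2 + 1), ] -
        m$values[mr, mcid, , drop = FALSE]
    }
    xs <- c(xs, x); ys <- c(ys, y); types <- c(types, m$dot_type)
  }
  img <- pmin(pmax(round_half_up(img), 0), 255)
  structure(list(image = img,
                 dots = data.frame(x = xs, y = ys, type = types,
                                   stringsAsFactors = FALSE),
                 seed = seed),
            class = "synthetic_patch")
}

# Build one perturbed dot mask according to a patch plan (consumes RNG).
sample_dot_mask <- function(plan) {
  t <- stats::runif(1, plan$colour_window[1], plan$colour_window[2])
  colour <- interpolate_primary_colour(t)
  m <- make_primary_dot_mask(colour)
  is_secondary <- plan$has_secondary && stats::runif(1) < plan$secondary_prob
  if (is_secondary) {
    s <- make_secondary_dot_mask()
    off <- c(sample(-1:1, 1), sample(-1:1, 1))
    m <- combine_masks(m, s, off)
  }
  params <- perturb_params(
    cardinal_stretch = sample(0:3, 4, replace = TRUE),
    base_scale_x = stats::runif(1, 0.25, 0.5),
    base_scale_y = stats::runif(1, 0.25, 0.5),
    shared_offset = sample_scale_offset(stats::runif(1)),
    rotation = sample(0:359, 1)
  )
  trim_mask(perturb_dot(m, params))
}

#' Generate one synthetic patch
#'
#' Full pipeline: per-patch plan, background texture, separated dot
#' placement, mask construction and perturbation, subtractive application.
#' Regenerating with the same seed reproduces the patch bit-exactly.
#'
#' @param seed integer seed.
#' @param shape `c(H, W)` (default 480x480).
#' @param background optional pre-existing HxWx3 8-bit BGR image to paint
#'   dots onto (e.g. a real tissue patch); default generates one.
#' @param existing_dots optional data frame of natural-dot coordinates
#'   (`x`, `y`) that placement must stay 3 px away from (a pluggable
#'   coordinate source, e.g. read from CSV).
#' @return a `synthetic_patch`.
#' @export
generate_patch <- function(seed, shape = c(480, 480), background = NULL,
                           existing_dots = NULL) {
  set.seed(seed)
  plan <- plan_patch()
  if (is.null(background)) background <- generate_background(shape)
  coords <- place_dots(plan$n, existing_dots, shape)
  masks <- lapply(seq_len(plan$n), function(i) {
    list(mask = sample_dot_mask(plan), x = coords$x[i], y = coords$y[i])
  })
  apply_dots(background, masks, seed = seed)
}
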