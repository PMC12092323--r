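# Training: overlap losses, ground-truth cross masks, augmentation,
# ImageNet normalization, patch subdivision, AdaDelta, and the phased
# curriculum with backbone freezing in phase 1.

#' Loss configuration
#'
#' @param kind one of `"tversky"`, `"dice"`, `"jaccard"`, `"bce"`.
#' @param alpha Tversky recall weight; the precision weight is `beta =
#'   1 - alpha`. Dice loss is Tversky with `alpha = 0.5`.
#' @param smooth smoothing constant added to numerator and denominator of
#'   the overlap losses.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(kind = c("tversky", "dice", "jaccard", "bce"),
                        alpha = 0.6, smooth = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(alpha >= 0, alpha <= 1, smooth > 0)
  if (kind == "dice") alpha <- 0.5
  structure(list(kind = kind, alpha = alpha, beta = 1 - alpha,
                 smooth = smooth), class = "loss_config")
}

#' Optimizer configuration
#'
#' AdaDelta with `rho = 0.975` and update scale 0.005 is the reference
#' full-scale training configuration. AdaDelta's accumulator warm-up makes
#' it very slow over short desk-scale runs, so an Adam variant is also
#' provided for small-budget experiments.
#'
#' @param kind `"adadelta"` (default) or `"adam"`.
#' @param rho AdaDelta decay rate of the squared-gradient and
#'   squared-update accumulators (default 0.975).
#' @param learning_rate update scale (AdaDelta default 0.005; a typical
#'   Adam value is 1e-3).
#' @param batch_size training batch size (default 4).
#' @param epsilon numerical stabilizer.
#' @param beta1,beta2 Adam moment decays.
#' @export
optimizer_config <- function(kind = c("adadelta", "adam"), rho = 0.975,
                             learning_rate = NULL, batch_size = 4,
                             epsilon = NULL, beta1 = 0.9, beta2 = 0.999) {
  kind <- match.arg(kind)
  if (is.null(learning_rate)) {
    learning_rate <- if (kind == "adadelta") 0.005 else 1e-3
  }
  if (is.null(epsilon)) epsilon <- if (kind == "adadelta") 1e-7 else 1e-8
  stopifnot(rho > 0, rho < 1, learning_rate > 0, batch_size >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(kind = kind, rho = rho, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epsilon = epsilon,
                 beta1 = beta1, beta2 = beta2),
            class = "optimizer_config")
}

# ---- losses -----------------------------------------------------------------

soft_counts <- function(pred, gt) {
  list(tp = sum(pred * gt),
       fn = sum((1 - pred) * gt),
       fp = sum(pred * (1 - gt)))
}

#' Tversky loss
#'
#' `1 - (TP + s) / (TP + alpha*FN + beta*FP + s)` with soft
#' (probabilistic) counts and `beta = 1 - alpha`. `alpha > 0.5` weights
#' recall over precision, suited to a rare positive class.
#'
#' @param pred probability map in `[0,1]`.
#' @param gt binary mask of the same shape.
#' @param alpha recall weight.
#' @param smooth smoothing constant.
#' @return scalar loss.
#' @export
tversky_loss <- function(pred, gt, alpha = 0.6, smooth = 1e-6) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop("pred and gt shapes differ")
  }
  ct <- soft_counts(pred, gt)
  1 - (ct$tp + smooth) / (ct$tp + alpha * ct$fn + (1 - alpha) * ct$fp + smooth)
}

# Gradient of Tversky loss w.r.t. pred.
tversky_grad <- function(pred, gt, alpha = 0.6, smooth = 1e-6) {
  ct <- soft_counts(pred, gt)
  den <- ct$tp + alpha * ct$fn + (1 - alpha) * ct$fp + smooth
  num <- ct$tp + smooth
  # dTP = g, dFN = -g, dFP = 1-g per pixel
  dden <- gt - alpha * gt + (1 - alpha) * (1 - gt)
  -(gt * den - num * dden) / den^2
}

#' Dice loss
#' @inheritParams tversky_loss
#' @export
dice_loss <- function(pred, gt, smooth = 1e-6) {
  tversky_loss(pred, gt, alpha = 0.5, smooth = smooth)
}

#' Jaccard loss
#'
#' `1 - (TP + s) / (TP + FP + FN + s)`.
#' @inheritParams tversky_loss
#' @export
jaccard_loss <- function(pred, gt, smooth = 1e-6) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop("pred and gt shapes differ")
  }
  ct <- soft_counts(pred, gt)
  1 - (ct$tp + smooth) / (ct$tp + ct$fp + ct$fn + smooth)
}

jaccard_grad <- function(pred, gt, smooth = 1e-6) {
  ct <- soft_counts(pred, gt)
  den <- ct$tp + ct$fp + ct$fn + smooth
  num <- ct$tp + smooth
  dden <- 1 - gt   # dTP+dFP+dFN = g + (1-g) - g... per pixel: g + (1-g) + (-g)
  -(gt * den - num * dden) / den^2
}

#' Binary cross-entropy loss
#'
#' Mean pixel-wise cross-entropy; predictions are clipped away from 0/1 for
#' numerical stability.
#' @inheritParams tversky_loss
#' @param eps clipping bound.
#' @export
bce_loss <- function(pred, gt, eps = 1e-7) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop("pred and gt shapes differ")
  }
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

bce_grad <- function(pred, gt, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  (-(gt / p) + (1 - gt) / (1 - p)) / length(pred)
}

loss_value <- function(cfg, pred, gt) {
  switch(cfg$kind,
         tversky = tversky_loss(pred, gt, cfg$alpha, cfg$smooth),
         dice = dice_loss(pred, gt, cfg$smooth),
         jaccard = jaccard_loss(pred, gt, cfg$smooth),
         bce = bce_loss(pred, gt))
}

loss_grad <- function(cfg, pred, gt) {
  switch(cfg$kind,
         tversky = tversky_grad(pred, gt, cfg$alpha, cfg$smooth),
         dice = tversky_grad(pred, gt, 0.5, cfg$smooth),
         jaccard = jaccard_grad(pred, gt, cfg$smooth),
         bce = bce_grad(pred, gt))
}

# ---- ground truth -----------------------------------------------------------

#' Render ground-truth cross masks
#'
#' Each dot contributes a 5-pixel plus/cross pattern (centre plus the four
#' 4-neighbours) of positive pixels, clipped at the image borders;
#' overlapping crosses take the union. The cross inflates the rare positive
#' class slightly, easing training under heavy class imbalance.
#'
#' @param dots data frame with 0-based integer columns `x`, `y`.
#' @param shape `c(H, W)`.
#' @return HxW binary (0/1) matrix.
#' @export
render_gt_mask <- function(dots, shape) {
  H <- shape[1]; W <- shape[2]
  m <- matrix(0, H, W)
  if (is.null(dots) || nrow(dots) == 0) return(m)
  if (any(dots$x < 0 | dots$x >= W | dots$y < 0 | dots$y >= H)) {
    stop("dot coordinate outside the image")
  }
  for (i in seq_len(nrow(dots))) {
    x <- dots$x[i]; y <- dots$y[i]
    pts <- rbind(c(y, x), c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))
    keep <- pts[, 1] >= 0 & pts[, 1] < H & pts[, 2] >= 0 & pts[, 2] < W
    pts <- pts[keep, , drop = FALSE]
    m[pts + 1L] <- 1
  }
  m
}

# ---- normalization ----------------------------------------------------------

# ImageNet channel statistics in RGB order.
IMAGENET_MEAN_RGB <- c(0.485, 0.456, 0.406)
IMAGENET_SD_RGB <- c(0.229, 0.224, 0.225)

#' ImageNet input normalization
#'
#' Scales an 8-bit image to `[0,1]` and standardizes each channel with the
#' canonical ImageNet statistics. Images in this package are stored in BGR
#' channel order, so the RGB statistics are applied reversed.
#'
#' @param image HxWx3 8-bit (0-255) BGR array.
#' @return HxWx3 float array.
#' @export
normalize_input <- function(image) {
  mean_bgr <- rev(IMAGENET_MEAN_RGB)
  sd_bgr <- rev(IMAGENET_SD_RGB)
  out <- image / 255
  for (c in 1:3) out[, , c] <- (out[, , c] - mean_bgr[c]) / sd_bgr[c]
  out
}

#' @rdname normalize_input
#' @export
denormalize_input <- function(image) {
  mean_bgr <- rev(IMAGENET_MEAN_RGB)
  sd_bgr <- rev(IMAGENET_SD_RGB)
  out <- image
  for (c in 1:3) out[, , c] <- out[, , c] * sd_bgr[c] + mean_bgr[c]
  out * 255
}

# ---- augmentation -----------------------------------------------------------

#' Augmentation configuration
#'
#' @param max_rotation_degrees maximum rotation angle (0-90).
#' @param allow_hflip,allow_vflip enable horizontal / vertical flips.
#' @export
augment_config <- function(max_rotation_degrees = 90, allow_hflip = TRUE,
                           allow_vflip = TRUE) {
  stopifnot(max_rotation_degrees >= 0, max_rotation_degrees <= 90)
  structure(list(max_rotation_degrees = max_rotation_degrees,
                 allow_hflip = allow_hflip, allow_vflip = allow_vflip),
            class = "augment_config")
}

# Rotate an HxW (or HxWxC) array about its centre by `angle` degrees.
# interp "bilinear" for images, "nearest" for binary masks; zero padding.
rotate_array <- function(a, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(a)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yy <- matrix(seq_len(H) - 1 - cy, H, W)
  xx <- matrix(rep(seq_len(W) - 1 - cx, each = H), H, W)
  # inverse mapping (sample source for each destination pixel)
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  sample_plane <- function(p) {
    if (interp == "nearest") {
      xi <- round(sx); yi <- round(sy)
      ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
      v <- matrix(0, H, W)
      v[ok] <- p[cbind(yi[ok] + 1, xi[ok] + 1)]
      return(v)
    }
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    v <- matrix(0, H, W)
    get <- function(yi, xi) {
      ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
      out <- matrix(0, H, W)
      out[ok] <- p[cbind(yi[ok] + 1, xi[ok] + 1)]
      out
    }
    v <- get(y0, x0) * (1 - fx) * (1 - fy) +
      get(y0, x0 + 1) * fx * (1 - fy) +
      get(y0 + 1, x0) * (1 - fx) * fy +
      get(y0 + 1, x0 + 1) * fx * fy
    v
  }
  if (length(d) == 2) return(sample_plane(a))
  out <- a
  for (c in seq_len(d[3])) out[, , c] <- sample_plane(a[, , c])
  out
}

#' Augment an image/mask pair
#'
#' Applies the same random geometric transform (rotation up to the
#' configured angle, then optional horizontal and/or vertical flips) to the
#' image and its mask. The image is resampled bilinearly, the mask with
#' nearest-neighbour so it stays binary.
#'
#' @param image HxWxC array.
#' @param mask HxW binary matrix.
#' @param config an [augment_config()].
#' @return list with `image` and `mask`.
#' @export
augment <- function(image, mask, config = augment_config()) {
  angle <- stats::runif(1, 0, config$max_rotation_degrees)
  if (angle > 1e-9) {
    image <- rotate_array(image, angle, "bilinear")
    mask <- rotate_array(mask, angle, "nearest")
  }
  if (config$allow_hflip && stats::runif(1) < 0.5) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (config$allow_vflip && stats::runif(1) < 0.5) {
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  list(image = image, mask = mask)
}

# ---- patch subdivision ------------------------------------------------------

#' Subdivide a large patch into network-sized tiles
#'
#' Training mode takes seeded random crops; evaluation mode tiles the patch
#' with a deterministic sliding grid (stride 128 covers a 480x480 patch with
#' a 3x3 grid of 224x224 tiles exactly). Dot coordinates are shifted into
#' each tile's frame; dots falling outside a tile are dropped.
#'
#' @param image HxWx3 array (H, W >= tile).
#' @param dots data frame with `x`, `y` (and optionally `type`).
#' @param mode `"train"` or `"eval"`.
#' @param tile tile side in pixels.
#' @param stride eval-mode grid stride.
#' @param n_crops number of random crops in train mode.
#' @return list of records `list(image, dots, origin = c(x, y))`.
#' @export
subdivide_patch <- function(image, dots = NULL, mode = c("eval", "train"),
                            tile = 224, stride = 128, n_crops = 4) {
  mode <- match.arg(mode)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < tile || W < tile) stop("image smaller than tile size")
  origins <- if (mode == "eval") {
    xs <- unique(c(seq(0, W - tile, by = stride), W - tile))
    ys <- unique(c(seq(0, H - tile, by = stride), H - tile))
    expand.grid(x = xs, y = ys)
  } else {
    data.frame(x = sample.int(W - tile + 1, n_crops, replace = TRUE) - 1,
               y = sample.int(H - tile + 1, n_crops, replace = TRUE) - 1)
  }
  lapply(seq_len(nrow(origins)), function(i) {
    ox <- origins$x[i]; oy <- origins$y[i]
    img <- image[(oy + 1):(oy + tile), (ox + 1):(ox + tile), , drop = FALSE]
    dt <- NULL
    if (!is.null(dots) && nrow(dots) > 0) {
      keep <- dots$x >= ox & dots$x < ox + tile & dots$y >= oy & dots$y < oy + tile
      dt <- dots[keep, , drop = FALSE]
      dt$x <- dt$x - ox
      dt$y <- dt$y - oy
      rownames(dt) <- NULL
    } else {
      dt <- data.frame(x = integer(0), y = integer(0))
    }
    list(image = img, dots = dt, origin = c(x = ox, y = oy))
  })
}

# ---- curriculum -------------------------------------------------------------

#' One phase of the training curriculum
#'
#' @param real_samples_per_epoch,generated_samples_per_epoch sample counts
#'   drawn each epoch.
#' @param epochs number of epochs in the phase.
#' @param backbone_frozen whether backbone weights are locked.
#' @export
phase_spec <- function(real_samples_per_epoch, generated_samples_per_epoch,
                       epochs, backbone_frozen = FALSE) {
  stopifnot(real_samples_per_epoch >= 0, generated_samples_per_epoch >= 0,
            epochs > 0)
  structure(list(real = as.integer(real_samples_per_epoch),
                 generated = as.integer(generated_samples_per_epoch),
                 epochs = as.integer(epochs),
                 backbone_frozen = isTRUE(backbone_frozen)),
            class = "phase_spec")
}

#' Default six-phase curriculum
#'
#' The generated-data curriculum: 460 real samples per epoch throughout
#' (115 real patches sampled 4x each), with the generated-sample count
#' halving each phase from 1071 down to 0, 128 epochs per phase except the
#' final 1024-epoch phase. Only phase 1 trains with the backbone frozen.
#'
#' @return list of six [phase_spec()] objects.
#' @export
default_schedule <- function() {
  list(phase_spec(460, 1071, 128, backbone_frozen = TRUE),
       phase_spec(460, 460, 128),
       phase_spec(460, 230, 128),
       phase_spec(460, 115, 128),
       phase_spec(460, 58, 128),
       phase_spec(460, 0, 1024))
}

# ---- optimizer --------------------------------------------------------------

optimizer_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e
}

# kept under its historical name for internal callers
adadelta_state <- optimizer_state

optimizer_step <- function(layers, state, cfg) {
  state$t <- state$t + 1L
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!length(l$params)) next
    if (!l$trainable) {
      zero_grads_layer(l)
      next
    }
    key <- paste0("L", i)
    st <- state[[key]]
    if (is.null(st)) {
      st <- list(Eg = lapply(l$params, function(p) p * 0),
                 Ed = lapply(l$params, function(p) p * 0))
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (cfg$kind == "adadelta") {
        st$Eg[[nm]] <- cfg$rho * st$Eg[[nm]] + (1 - cfg$rho) * g^2
        upd <- g * sqrt(st$Ed[[nm]] + cfg$epsilon) /
          sqrt(st$Eg[[nm]] + cfg$epsilon)
        st$Ed[[nm]] <- cfg$rho * st$Ed[[nm]] + (1 - cfg$rho) * upd^2
        l$params[[nm]] <- l$params[[nm]] - cfg$learning_rate * upd
      } else {
        st$Ed[[nm]] <- cfg$beta1 * st$Ed[[nm]] + (1 - cfg$beta1) * g
        st$Eg[[nm]] <- cfg$beta2 * st$Eg[[nm]] + (1 - cfg$beta2) * g^2
        mh <- st$Ed[[nm]] / (1 - cfg$beta1^state$t)
        vh <- st$Eg[[nm]] / (1 - cfg$beta2^state$t)
        l$params[[nm]] <- l$params[[nm]] -
          cfg$learning_rate * mh / (sqrt(vh) + cfg$epsilon)
      }
    }
    state[[key]] <- st
    zero_grads_layer(l)
  }
  invisible(state)
}

# historical alias
adadelta_step <- function(layers, state, cfg) optimizer_step(layers, state, cfg)

# ---- training loop ----------------------------------------------------------

binary_iou <- function(pred, gt, threshold = 0.5) {
  p <- pred > threshold
  g <- gt > 0.5
  inter <- sum(p & g)
  uni <- sum(p | g)
  if (uni == 0) return(1)
  inter / uni
}

prepare_sample <- function(sample, input_size, augment_cfg) {
  img <- sample$image
  H <- dim(img)[1]
  if (H > input_size) {
    tiles <- subdivide_patch(img, sample$dots, mode = "train",
                             tile = input_size, n_crops = 1)
    img <- tiles[[1]]$image
    dots <- tiles[[1]]$dots
  } else {
    dots <- sample$dots
  }
  mask <- render_gt_mask(dots, dim(img)[1:2])
  if (!is.null(augment_cfg)) {
    au <- augment(img, mask, augment_cfg)
    img <- au$image
    mask <- au$mask
  }
  list(image = normalize_input(img), mask = mask)
}

#' Train the segmentation network
#'
#' Runs the phased curriculum: each epoch draws the phase's real and
#' generated sample counts (real patches are cycled so each is seen the same
#' number of times per epoch; generated patches are drawn without
#' replacement), augments, normalizes, and optimizes with AdaDelta. Backbone
#' freezing follows each phase's flag. The run is fully seeded.
#'
#' @param model an `rnascope_model` from [build_network()].
#' @param real_data,generated_data lists of samples, each
#'   `list(image = HxWx3 8-bit BGR array, dots = data.frame(x, y))`.
#' @param schedule list of [phase_spec()]; default [default_schedule()].
#' @param loss a [loss_config()].
#' @param optimizer an [optimizer_config()].
#' @param seed integer seed controlling sampling, augmentation and
#'   regularization noise.
#' @param validation optional list of samples for per-epoch IoU (computed at
#'   probability threshold 0.5 on the raw maps).
#' @param augment_cfg an [augment_config()], or `NULL` to disable.
#' @param verbose print per-epoch progress.
#' @return the model, with a `history` data frame attached
#'   (`attr(model, "history")` columns phase, epoch, loss, val_iou).
#' @export
train <- function(model, real_data, generated_data = list(),
                  schedule = default_schedule(),
                  loss = loss_config("tversky", alpha = 0.6),
                  optimizer = optimizer_config(),
                  seed = 1L, validation = NULL,
                  augment_cfg = augment_config(), verbose = FALSE) {
  if (length(real_data) == 0) stop("real_data is empty")
  set.seed(seed)
  state <- adadelta_state()
  layers <- model_layers(model)
  input_size <- model$config$input_size
  hist <- list()
  for (pi in seq_along(schedule)) {
    ph <- schedule[[pi]]
    if (ph$generated > length(generated_data)) {
      stop("phase ", pi, " needs ", ph$generated,
           " generated patches but only ", length(generated_data),
           " are available")
    }
    freeze_backbone(model, ph$backbone_frozen)
    for (ep in seq_len(ph$epochs)) {
      idx_real <- if (ph$real > 0) {
        rep(seq_along(real_data), length.out = ph$real)
      } else integer(0)
      idx_gen <- if (ph$generated > 0) {
        sample(seq_along(generated_data), ph$generated)
      } else integer(0)
      pool <- c(lapply(idx_real, function(i) real_data[[i]]),
                lapply(idx_gen, function(i) generated_data[[i]]))
      ord <- sample(length(pool))
      ep_loss <- 0
      nb <- 0
      for (bstart in seq(1, length(ord), by = optimizer$batch_size)) {
        bidx <- ord[bstart:min(bstart + optimizer$batch_size - 1, length(ord))]
        prepped <- lapply(pool[bidx], prepare_sample, input_size = input_size,
                          augment_cfg = augment_cfg)
        x <- images_to_tensor(lapply(prepped, `[[`, "image"))
        g <- masks_to_tensor(lapply(prepped, `[[`, "mask"))
        y <- model_forward(model, x, training = TRUE)
        ep_loss <- ep_loss + loss_value(loss, y, g)
        dy <- loss_grad(loss, y, g)
        model_backward(model, dy)
        adadelta_step(layers, state, optimizer)
        nb <- nb + 1
      }
      val_iou <- NA_real_
      if (!is.null(validation)) {
        ious <- vapply(validation, function(s) {
          pm <- predict_map(model, normalize_input(s$image))
          binary_iou(pm, render_gt_mask(s$dots, dim(s$image)[1:2]))
        }, numeric(1))
        val_iou <- mean(ious)
      }
      hist[[length(hist) + 1]] <- data.frame(phase = pi, epoch = ep,
                                             loss = ep_loss / nb,
                                             val_iou = val_iou)
      if (verbose) {
        message(sprintf("phase %d epoch %d loss %.4f val_iou %s", pi, ep,
                        ep_loss / nb,
                        ifelse(is.na(val_iou), "-", sprintf("%.3f", val_iou))))
      }
    }
  }
  freeze_backbone(model, FALSE)
  attr(model, "history") <- do.call(rbind, hist)
  model
}
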