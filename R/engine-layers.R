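# Minimal CNN engine: layer objects with explicit forward/backward passes.
#
# Internal tensor layout is (C, H, W, N) double arrays (channels fastest),
# which makes pointwise convolutions plain BLAS matrix products and keeps
# the C++ kernels (dense/depthwise/transpose convolution) cache-friendly.
# Each layer is an environment holding parameters, accumulated gradients,
# and the forward-pass cache needed by its backward pass.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$trainable <- TRUE
  e$params <- list()
  e$grads <- list()
  e$cache <- NULL
  class(e) <- "nn_layer"
  e
}

#' @noRd
init_weight <- function(dims, std = 0.02) {
  array(stats::rnorm(prod(dims), 0, std), dim = dims)
}

zero_grads_layer <- function(layer) {
  layer$grads <- lapply(layer$params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  invisible(layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

acc_grad <- function(layer, name, g) {
  layer$grads[[name]] <- layer$grads[[name]] + g
}

as_cmat <- function(x) {
  d <- dim(x)
  matrix(x, nrow = d[1], ncol = prod(d[-1]))
}

restore_dim <- function(m, d) {
  dim(m) <- d
  m
}

# ---- dense convolution (stem, downsampling) --------------------------------

layer_conv2d <- function(cin, cout, k, stride = 1, pad = 0, std = 0.02,
                         bias_init = 0) {
  l <- new_layer("conv2d")
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$params <- list(W = init_weight(c(cout, cin, k, k), std),
                   b = rep(bias_init, cout))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    cpp_conv2d(x, l$params$W, l$params$b, l$stride, l$pad)
  }
  l$bwd <- function(dy) {
    g <- cpp_conv2d_bwd(l$cache, l$params$W, dy, l$stride, l$pad)
    acc_grad(l, "W", g$dw); acc_grad(l, "b", g$db)
    g$dx
  }
  l
}

# ---- pointwise (1x1) convolution: pure GEMM --------------------------------

layer_pwconv <- function(cin, cout, std = 0.02, bias_init = 0) {
  l <- new_layer("pwconv")
  l$params <- list(W = init_weight(c(cout, cin), std), b = rep(bias_init, cout))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    cpp_pwconv(x, l$params$W, l$params$b)
  }
  l$bwd <- function(dy) {
    g <- cpp_pwconv_bwd(l$cache, l$params$W, dy)
    acc_grad(l, "W", g$dw)
    acc_grad(l, "b", g$db)
    g$dx
  }
  l
}

# ---- depthwise convolution --------------------------------------------------

layer_dwconv <- function(ch, k = 7, std = 0.02) {
  l <- new_layer("dwconv")
  l$params <- list(W = init_weight(c(ch, k, k), std), b = rep(0, ch))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    cpp_dwconv(x, l$params$W, l$params$b)
  }
  l$bwd <- function(dy) {
    g <- cpp_dwconv_bwd(l$cache, l$params$W, dy)
    acc_grad(l, "W", g$dw); acc_grad(l, "b", g$db)
    g$dx
  }
  l
}

# ---- 2x2 stride-2 transpose convolution ------------------------------------

layer_tconv <- function(cin, cout, std = 0.02) {
  l <- new_layer("tconv")
  l$params <- list(W = init_weight(c(cout, cin, 2, 2), std), b = rep(0, cout))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    cpp_tconv2(x, l$params$W, l$params$b)
  }
  l$bwd <- function(dy) {
    g <- cpp_tconv2_bwd(l$cache, l$params$W, dy)
    acc_grad(l, "W", g$dw); acc_grad(l, "b", g$db)
    g$dx
  }
  l
}

# ---- normalization ----------------------------------------------------------

# Layer normalization across the channel axis (per spatial position & sample),
# the ConvNeXt convention.
layer_layernorm <- function(ch, eps = 1e-6) {
  l <- new_layer("layernorm")
  l$eps <- eps
  l$params <- list(gamma = rep(1, ch), beta = rep(0, ch))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    out <- cpp_layernorm(x, l$params$gamma, l$params$beta, l$eps)
    l$cache <- out
    out$y
  }
  l$bwd <- function(dy) {
    g <- cpp_layernorm_bwd(l$cache$xhat, l$cache$ivar, l$params$gamma, dy)
    acc_grad(l, "gamma", g$dgamma)
    acc_grad(l, "beta", g$dbeta)
    g$dx
  }
  l
}

# Batch normalization across (H, W, N) per channel. When the layer is frozen
# (backbone locked) the running statistics are used even in training mode and
# are not updated.
layer_batchnorm <- function(ch, eps = 1e-5, momentum = 0.9) {
  l <- new_layer("batchnorm")
  l$eps <- eps; l$momentum <- momentum
  l$params <- list(gamma = rep(1, ch), beta = rep(0, ch))
  l$run_mean <- rep(0, ch)
  l$run_var <- rep(1, ch)
  zero_grads_layer(l)
  # channel-first layout: length-C vectors recycle along the channel axis,
  # so all per-channel arithmetic runs directly on the 4-D arrays
  l$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    C <- d[1]; M <- length(x) / C
    use_batch <- training && l$trainable
    if (use_batch) {
      mu <- .rowMeans(x, C, M)
      xc <- x - mu
      v <- .rowMeans(xc * xc, C, M)
      l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
      l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
    } else {
      mu <- l$run_mean
      v <- l$run_var
      xc <- x - mu
    }
    ivar <- 1 / sqrt(v + l$eps)
    xhat <- xc * ivar
    l$cache <- list(xhat = xhat, ivar = ivar, d = d, batch = use_batch)
    l$params$gamma * xhat + l$params$beta
  }
  l$bwd <- function(dy) {
    xhat <- l$cache$xhat
    C <- l$cache$d[1]; M <- length(dy) / C
    acc_grad(l, "gamma", .rowSums(dy * xhat, C, M))
    acc_grad(l, "beta", .rowSums(dy, C, M))
    dxh <- dy * l$params$gamma
    if (l$cache$batch) {
      m1 <- .rowMeans(dxh, C, M)
      m2 <- .rowMeans(dxh * xhat, C, M)
      (dxh - m1 - xhat * m2) * l$cache$ivar
    } else {
      dxh * l$cache$ivar
    }
  }
  l
}

# ---- activations ------------------------------------------------------------

layer_gelu <- function() {
  l <- new_layer("gelu")
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    out <- cpp_gelu(x)
    l$cache <- list(x = x, phi = out$phi)
    out$y
  }
  l$bwd <- function(dy) cpp_gelu_bwd(l$cache$x, l$cache$phi, dy)
  l
}

layer_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    y <- 1 / (1 + exp(-x))
    l$cache <- y
    y
  }
  l$bwd <- function(dy) dy * l$cache * (1 - l$cache)
  l
}

# ---- per-channel scaling (ConvNeXt layer scale) ----------------------------

layer_layerscale <- function(ch, init = 1e-6) {
  l <- new_layer("layerscale")
  l$params <- list(gamma = rep(init, ch))
  zero_grads_layer(l)
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    x * l$params$gamma   # gamma recycles along the channel-first axis
  }
  l$bwd <- function(dy) {
    C <- dim(dy)[1]
    acc_grad(l, "gamma", .rowSums(dy * l$cache, C, length(dy) / C))
    dy * l$params$gamma
  }
  l
}

# ---- stochastic regularization ---------------------------------------------

layer_dropout <- function(rate) {
  l <- new_layer("dropout")
  l$rate <- rate
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    if (!training || l$rate <= 0) {
      l$cache <- NULL
      return(x)
    }
    keep <- 1 - l$rate
    m <- array(stats::rbinom(length(x), 1, keep) / keep, dim = dim(x))
    l$cache <- m
    x * m
  }
  l$bwd <- function(dy) {
    if (is.null(l$cache)) dy else dy * l$cache
  }
  l
}

# Stochastic depth: drops the whole residual branch per sample.
layer_droppath <- function(rate) {
  l <- new_layer("droppath")
  l$rate <- rate
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    if (!training || l$rate <= 0) {
      l$cache <- NULL
      return(x)
    }
    d <- dim(x)
    keep <- 1 - l$rate
    m <- stats::rbinom(d[4], 1, keep) / keep
    l$cache <- m
    y <- x
    for (n in seq_len(d[4])) y[, , , n] <- y[, , , n] * m[n]
    y
  }
  l$bwd <- function(dy) {
    if (is.null(l$cache)) return(dy)
    d <- dim(dy)
    for (n in seq_len(d[4])) dy[, , , n] <- dy[, , , n] * l$cache[n]
    dy
  }
  l
}

# ---- sequential container ---------------------------------------------------

seq_container <- function(layers, kind = "sequential") {
  l <- new_layer(kind)
  l$layers <- layers
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    for (ly in l$layers) x <- ly$fwd(x, training)
    x
  }
  l$bwd <- function(dy) {
    for (ly in rev(l$layers)) dy <- ly$bwd(dy)
    dy
  }
  l
}

# Recursively collect leaf layers (those owning parameters or state).
collect_layers <- function(obj) {
  if (!is.null(obj$layers)) {
    unlist(lapply(obj$layers, collect_layers), recursive = FALSE)
  } else {
    list(obj)
  }
}

# Flat inventory of layer kinds, nested containers expanded in order.
layer_inventory <- function(obj) {
  vapply(collect_layers(obj), function(l) l$kind, character(1))
}
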