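# Network architecture: ConvNeXt-style backbone, custom regularized
# upscaling blocks, nested U-Net++ decoder below the 4x stem, and a
# two-stage 4x final upsampler ending in a sigmoid segmentation map.

BACKBONE_PRESETS <- list(
  # "tiny" is a reduced desk-scale preset for CPU experiments and tests;
  # it is NOT the published ConvNeXt-T configuration.
  tiny  = list(depths = c(2, 2, 4, 2),  widths = c(32, 64, 128, 256)),
  small = list(depths = c(3, 3, 27, 3), widths = c(96, 192, 384, 768)),
  base  = list(depths = c(3, 3, 27, 3), widths = c(128, 256, 512, 1024))
)

#' Network configuration
#'
#' Collects every architecture hyperparameter of the segmentation network:
#' backbone size, the DropPath probability `d` used inside backbone blocks,
#' the DropOut probability `r` used inside the custom upscaling blocks, and
#' the regularization mode of the final 4x upsampling section.
#'
#' @param backbone_size one of `"tiny"`, `"small"`, `"base"`. `"base"` is the
#'   reference configuration (stage depths 3/3/27/3, widths
#'   128/256/512/1024); `"tiny"` is a reduced desk-scale preset
#'   (depths 2/2/4/2, widths 32/64/128/256) for CPU-bound experiments.
#' @param backbone_droppath DropPath (stochastic depth) probability `d`
#'   applied inside backbone blocks, linearly scaled with depth up to `d`.
#' @param upscale_dropout DropOut probability `r` inside the custom
#'   upscaling blocks of the nested decoder.
#' @param final_section_mode regularization of the final 4x upsampler:
#'   `"none"`, `"dropout"` (DropOut between its ConvNeXt blocks) or
#'   `"droppath"` (DropPath inside them).
#' @param final_section_rate probability used by `final_section_mode`.
#' @param input_size expected square input size in pixels; must be divisible
#'   by 32.
#' @return an object of class `network_config`.
#' @export
network_config <- function(backbone_size = "base",
                           backbone_droppath = 0.2,
                           upscale_dropout = 0.15,
                           final_section_mode = c("none", "dropout", "droppath"),
                           final_section_rate = 0.15,
                           input_size = 224) {
  final_section_mode <- match.arg(final_section_mode)
  if (!backbone_size %in% names(BACKBONE_PRESETS)) {
    stop("unknown backbone_size: ", backbone_size)
  }
  stopifnot(backbone_droppath >= 0, backbone_droppath < 1,
            upscale_dropout >= 0, upscale_dropout < 1,
            final_section_rate >= 0, final_section_rate < 1)
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  structure(list(backbone_size = backbone_size,
                 backbone_droppath = backbone_droppath,
                 upscale_dropout = upscale_dropout,
                 final_section_mode = final_section_mode,
                 final_section_rate = final_section_rate,
                 input_size = input_size,
                 output_channels = 1L),
            class = "network_config")
}

#' ConvNeXt block
#'
#' Residual block: 7x7 depthwise convolution, layer normalization (channel
#' axis), pointwise 4x expansion, GELU, pointwise projection, per-channel
#' layer scale, and DropPath on the residual branch.
#'
#' @param width channel count (preserved by the block).
#' @param droppath_rate stochastic-depth probability for the branch.
#' @return a block object usable as a layer (fields `fwd`, `bwd`, `layers`).
#' @export
build_convnext_block <- function(width, droppath_rate = 0) {
  stopifnot(width > 0)
  branch <- seq_container(list(
    layer_dwconv(width, 7),
    layer_layernorm(width),
    layer_pwconv(width, 4 * width),
    layer_gelu(),
    layer_pwconv(4 * width, width),
    layer_layerscale(width),
    layer_droppath(droppath_rate)
  ))
  l <- new_layer("convnext_block")
  l$layers <- branch$layers
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    l$cache <- NULL
    x + branch$fwd(x, training)
  }
  l$bwd <- function(dy) dy + branch$bwd(dy)
  l
}

#' Custom upscaling block
#'
#' The ConvNeXt block variant used in the decoder: layer normalization is
#' replaced by batch normalization, a second batch normalization sits on the
#' skip-connection path, DropOut (not DropPath) is applied to the branch
#' before it rejoins the skip, and an activation is appended at the very end
#' of the block.
#'
#' @param width channel count.
#' @param dropout_rate DropOut probability applied before the skip join.
#' @return a block object usable as a layer.
#' @export
build_upscale_block <- function(width, dropout_rate = 0) {
  stopifnot(width > 0)
  branch <- seq_container(list(
    layer_dwconv(width, 7),
    layer_batchnorm(width),
    layer_pwconv(width, 4 * width),
    layer_gelu(),
    layer_pwconv(4 * width, width),
    layer_layerscale(width),
    layer_dropout(dropout_rate)
  ))
  skip_bn <- layer_batchnorm(width)
  out_act <- layer_gelu()
  l <- new_layer("upscale_block")
  l$layers <- c(branch$layers, list(skip_bn, out_act))
  l$params <- list()
  l$fwd <- function(x, training = FALSE) {
    out_act$fwd(skip_bn$fwd(x, training) + branch$fwd(x, training), training)
  }
  l$bwd <- function(dy) {
    dz <- out_act$bwd(dy)
    skip_bn$bwd(dz) + branch$bwd(dz)
  }
  l
}

# DropPath rates scale linearly over the backbone depth up to d, the
# stochastic-depth convention ConvNeXt inherits.
droppath_schedule <- function(total, d) {
  if (total == 1) return(d)
  d * (seq_len(total) - 1) / (total - 1)
}

#' Build the ConvNeXt backbone
#'
#' Stem (4x4 stride-4 convolution + layer normalization) followed by four
#' stages of ConvNeXt blocks separated by 2x downsampling layers, emitting
#' feature-map endpoints at 1/4, 1/8, 1/16 and 1/32 of the input resolution.
#'
#' @param config a [network_config()].
#' @return a backbone object with `fwd(x, training)` returning the list of 4
#'   endpoints and `bwd(dends)` accepting their gradients.
#' @export
build_backbone <- function(config) {
  preset <- BACKBONE_PRESETS[[config$backbone_size]]
  depths <- preset$depths
  widths <- preset$widths
  rates <- droppath_schedule(sum(depths), config$backbone_droppath)
  stem <- seq_container(list(
    layer_conv2d(3, widths[1], k = 4, stride = 4, pad = 0),
    layer_layernorm(widths[1])
  ), kind = "stem")
  stages <- list()
  downs <- list()
  bi <- 0
  for (s in 1:4) {
    blocks <- lapply(seq_len(depths[s]), function(j) {
      build_convnext_block(widths[s], rates[bi + j])
    })
    bi <- bi + depths[s]
    stages[[s]] <- seq_container(blocks, kind = paste0("stage", s))
    if (s < 4) {
      downs[[s]] <- seq_container(list(
        layer_layernorm(widths[s]),
        layer_conv2d(widths[s], widths[s + 1], k = 2, stride = 2, pad = 0)
      ), kind = paste0("down", s))
    }
  }
  b <- new_layer("backbone")
  b$layers <- c(list(stem), stages[1], downs[1], stages[2], downs[2],
                stages[3], downs[3], stages[4])
  b$widths <- widths
  b$params <- list()
  b$fwd <- function(x, training = FALSE) {
    e <- vector("list", 4)
    h <- stem$fwd(x, training)
    for (s in 1:4) {
      h <- stages[[s]]$fwd(h, training)
      e[[s]] <- h
      if (s < 4) h <- downs[[s]]$fwd(h, training)
    }
    e
  }
  b$bwd <- function(dends) {
    dh <- NULL
    for (s in 4:1) {
      g <- dends[[s]]
      if (!is.null(dh)) g <- g + downs[[s]]$bwd(dh)
      dh <- stages[[s]]$bwd(g)
    }
    stem$bwd(dh)
  }
  b
}

# Channel-axis concatenation with cached split sizes for the backward pass.
concat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[1], integer(1))
  out <- array(0, dim = c(sum(cs), d1[2], d1[3], d1[4]))
  om <- do.call(rbind, lapply(xs, as_cmat))
  restore_dim(om, dim(out))
}

split_channels <- function(dy, cs) {
  dm <- as_cmat(dy)
  d <- dim(dy)
  offs <- cumsum(c(0, cs))
  lapply(seq_along(cs), function(i) {
    restore_dim(dm[(offs[i] + 1):offs[i + 1], , drop = FALSE],
                c(cs[i], d[2], d[3], d[4]))
  })
}

#' Build the nested U-Net++ decoder
#'
#' Applies the U-Net++ node grid over the four backbone levels below the 4x
#' stem. Node `X[i,j]` receives the channel-wise concatenation of all
#' same-level predecessors `X[i,0..j-1]` and the 2x-upsampled (transpose
#' convolution) output of `X[i+1,j-1]`, projects to the level width with a
#' pointwise convolution, and applies one custom upscaling block. The top
#' node `X[0,3]` is returned at 1/4 resolution.
#'
#' @param backbone a backbone built by [build_backbone()] (used for widths).
#' @param config a [network_config()].
#' @return a decoder object with `fwd(endpoints, training)` and
#'   `bwd(dout)` returning per-endpoint gradients.
#' @export
build_nested_decoder <- function(backbone, config) {
  w <- backbone$widths
  r <- config$upscale_dropout
  nodes <- list()     # keyed "i.j" (0-based level i, column j)
  ups <- list()
  projs <- list()
  for (j in 1:3) {
    for (i in 0:(3 - j)) {
      key <- paste(i, j, sep = ".")
      ups[[key]] <- layer_tconv(w[i + 2], w[i + 1])
      in_ch <- j * w[i + 1] + w[i + 1]   # j same-level inputs + upsampled
      projs[[key]] <- layer_pwconv(in_ch, w[i + 1])
      nodes[[key]] <- build_upscale_block(w[i + 1], r)
    }
  }
  dec <- new_layer("nested_decoder")
  dec$layers <- c(unname(ups), unname(projs), unname(nodes))
  dec$params <- list()
  dec$node_count <- length(nodes)
  dec$fwd <- function(endpoints, training = FALSE) {
    if (length(endpoints) != 4) stop("decoder expects 4 backbone endpoints")
    for (i in 1:3) {
      di <- dim(endpoints[[i]])
      dn <- dim(endpoints[[i + 1]])
      if (di[2] != 2 * dn[2] || di[3] != 2 * dn[3]) {
        stop("backbone endpoints must have strictly halving resolutions")
      }
    }
    X <- list()
    for (i in 0:3) X[[paste(i, 0, sep = ".")]] <- endpoints[[i + 1]]
    cs_cache <- list()
    for (j in 1:3) {
      for (i in 0:(3 - j)) {
        key <- paste(i, j, sep = ".")
        below <- X[[paste(i + 1, j - 1, sep = ".")]]
        upped <- ups[[key]]$fwd(below, training)
        same <- lapply(0:(j - 1), function(k) X[[paste(i, k, sep = ".")]])
        inputs <- c(same, list(upped))
        cs_cache[[key]] <- vapply(inputs, function(x) dim(x)[1], integer(1))
        h <- concat_channels(inputs)
        h <- projs[[key]]$fwd(h, training)
        X[[key]] <- nodes[[key]]$fwd(h, training)
      }
    }
    dec$cache <- list(cs = cs_cache)
    X[["0.3"]]
  }
  dec$bwd <- function(dout) {
    grads <- list()
    addg <- function(key, g) {
      grads[[key]] <<- if (is.null(grads[[key]])) g else grads[[key]] + g
    }
    addg("0.3", dout)
    for (j in 3:1) {
      for (i in (3 - j):0) {
        key <- paste(i, j, sep = ".")
        g <- nodes[[key]]$bwd(grads[[key]])
        g <- projs[[key]]$bwd(g)
        parts <- split_channels(g, dec$cache$cs[[key]])
        for (k in 0:(j - 1)) addg(paste(i, k, sep = "."), parts[[k + 1]])
        dbelow <- ups[[key]]$bwd(parts[[j + 1]])
        addg(paste(i + 1, j - 1, sep = "."), dbelow)
      }
    }
    lapply(0:3, function(i) grads[[paste(i, 0, sep = ".")]])
  }
  dec
}

#' Build the final 4x upsampling section
#'
#' Twice over: a stride-2 transpose convolution doubling resolution followed
#' by 3 ConvNeXt blocks; then a pointwise projection to one channel and a
#' sigmoid, producing a full-resolution segmentation map in `[0,1]`.
#' Channel widths halve at each upsample (floored at 8).
#'
#' @param in_width channel count of the 1/4-resolution feature map.
#' @param config a [network_config()].
#' @return a section object with `fwd`/`bwd`.
#' @export
build_final_section <- function(in_width, config) {
  mode <- config$final_section_mode
  rate <- config$final_section_rate
  dp <- if (mode == "droppath") rate else 0
  widths <- c(max(in_width %/% 2, 8), max(in_width %/% 4, 8))
  mk_stage <- function(cin, cout) {
    layers <- list(layer_tconv(cin, cout))
    for (b in 1:3) {
      layers <- c(layers, list(build_convnext_block(cout, dp)))
      if (mode == "dropout" && b < 3) {
        layers <- c(layers, list(layer_dropout(rate)))
      }
    }
    layers
  }
  head <- layer_pwconv(widths[2], 1, bias_init = -4)
  sig <- layer_sigmoid()
  fs <- seq_container(c(mk_stage(in_width, widths[1]),
                        mk_stage(widths[1], widths[2]),
                        list(head, sig)),
                      kind = "final_section")
  fs
}

#' Build the full segmentation network
#'
#' Composes backbone, nested U-Net++ decoder, and the final 4x upsampler
#' into a model mapping an HxWx3 input to an HxW segmentation map in
#' `[0,1]` (H, W divisible by 32). The backbone can be frozen ("locked") so
#' that only the decoder and final section train.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `rnascope_model`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  backbone <- build_backbone(config)
  decoder <- build_nested_decoder(backbone, config)
  final <- build_final_section(backbone$widths[1], config)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$backbone <- backbone
  model$decoder <- decoder
  model$final <- final
  model$sections <- list(backbone = backbone, decoder = decoder, final = final)
  class(model) <- "rnascope_model"
  model
}

# Forward pass on engine-layout input (3,H,W,N); returns (1,H,W,N).
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0) {
    stop("input spatial size must be divisible by 32")
  }
  e <- model$backbone$fwd(x, training)
  h <- model$decoder$fwd(e, training)
  model$final$fwd(h, training)
}

# Backward pass; dy has the output's shape. Returns gradient w.r.t. input.
model_backward <- function(model, dy) {
  dh <- model$final$bwd(dy)
  dends <- model$decoder$bwd(dh)
  model$backbone$bwd(dends)
}

#' Predict a segmentation map
#'
#' Runs the network in inference mode on one image.
#'
#' @param model an `rnascope_model`.
#' @param image HxWx3 numeric array, already normalized
#'   (see [normalize_input()]).
#' @return HxW matrix of probabilities in `[0,1]`.
#' @export
predict_map <- function(model, image) {
  x <- images_to_tensor(list(image))
  y <- model_forward(model, x, training = FALSE)
  matrix(y[1, , , 1], nrow = dim(y)[2], ncol = dim(y)[3])
}

# Convert a list of HxWxC images to engine layout (C,H,W,N).
images_to_tensor <- function(images) {
  d <- dim(images[[1]])
  out <- array(0, dim = c(d[3], d[1], d[2], length(images)))
  for (n in seq_along(images)) out[, , , n] <- aperm(images[[n]], c(3, 1, 2))
  out
}

masks_to_tensor <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0, dim = c(1, d[1], d[2], length(masks)))
  for (n in seq_along(masks)) out[1, , , n] <- masks[[n]]
  out
}

#' Freeze or unfreeze the backbone
#'
#' When frozen, backbone parameters receive no optimizer updates and its
#' normalization layers keep using (and stop updating) running statistics.
#'
#' @param model an `rnascope_model`.
#' @param frozen logical.
#' @export
freeze_backbone <- function(model, frozen = TRUE) {
  for (l in collect_layers(model$backbone)) l$trainable <- !frozen
  invisible(model)
}

#' Parameter counts
#'
#' @param model an `rnascope_model`.
#' @return named list with total, trainable and per-section parameter counts.
#' @export
count_params <- function(model) {
  sec <- lapply(model$sections, function(s) {
    ls <- collect_layers(s)
    total <- sum(vapply(ls, function(l) sum(lengths(l$params)), numeric(1)))
    train <- sum(vapply(ls, function(l) {
      if (l$trainable) sum(lengths(l$params)) else 0
    }, numeric(1)))
    c(total = total, trainable = train)
  })
  list(total = sum(vapply(sec, `[[`, numeric(1), "total")),
       trainable = sum(vapply(sec, `[[`, numeric(1), "trainable")),
       sections = sec)
}

model_layers <- function(model) {
  unlist(lapply(model$sections, collect_layers), recursive = FALSE)
}

#' Extract model weights
#'
#' @param model an `rnascope_model`.
#' @param section `"all"` or one of `"backbone"`, `"decoder"`, `"final"`.
#' @return list of per-layer parameter lists, with layer kinds attached.
#' @export
get_weights <- function(model, section = "all") {
  ls <- if (section == "all") model_layers(model) else
    collect_layers(model$sections[[section]])
  out <- lapply(ls, function(l) {
    p <- l$params
    if (l$kind == "batchnorm") {
      p$run_mean <- l$run_mean
      p$run_var <- l$run_var
    }
    p
  })
  attr(out, "kinds") <- vapply(ls, function(l) l$kind, character(1))
  out
}

set_weights <- function(model, weights, section = "all") {
  ls <- if (section == "all") model_layers(model) else
    collect_layers(model$sections[[section]])
  if (length(ls) != length(weights)) {
    stop("weight list length mismatch: model has ", length(ls),
         " layers, source has ", length(weights))
  }
  for (i in seq_along(ls)) {
    l <- ls[[i]]
    w <- weights[[i]]
    for (nm in names(l$params)) {
      if (is.null(w[[nm]])) stop("missing parameter ", nm, " at layer ", i)
      if (length(w[[nm]]) != length(l$params[[nm]])) {
        stop("shape mismatch at layer ", i, " (", l$kind, "), parameter ", nm,
             ": expected ", length(l$params[[nm]]), " values, got ",
             length(w[[nm]]))
      }
      pv <- w[[nm]]
      if (!is.null(dim(l$params[[nm]]))) dim(pv) <- dim(l$params[[nm]])
      l$params[[nm]] <- pv
    }
    if (l$kind == "batchnorm") {
      if (!is.null(w$run_mean)) l$run_mean <- w$run_mean
      if (!is.null(w$run_var)) l$run_var <- w$run_var
    }
  }
  invisible(model)
}

#' Load backbone weights
#'
#' Replaces backbone parameters from a checkpoint file or another model's
#' extracted backbone weights; all non-backbone parameters are untouched.
#' With a `NULL` source the random initialization is kept and a notice is
#' emitted (pretrained weights are optional, never required).
#'
#' @param model an `rnascope_model`.
#' @param weights_source `NULL`, a file path to a checkpoint saved by
#'   [save_model()], or a weight list from [get_weights()].
#' @return the model, invisibly.
#' @export
load_backbone_weights <- function(model, weights_source = NULL) {
  if (is.null(weights_source)) {
    message("no backbone weights supplied; keeping random initialization")
    return(invisible(model))
  }
  w <- weights_source
  if (is.character(w)) {
    ck <- readRDS(w)
    w <- if (!is.null(ck$weights_backbone)) ck$weights_backbone else ck$weights
  }
  set_weights(model, w, section = "backbone")
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the serializable [network_config()] plus all weights
#' (including batch-normalization running statistics).
#'
#' @param model an `rnascope_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               weights = get_weights(model, "all"),
               weights_backbone = get_weights(model, "backbone")),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$config[setdiff(names(ck$config),
                                                   "output_channels")])
  model <- build_network(cfg)
  set_weights(model, ck$weights, "all")
  model
}
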