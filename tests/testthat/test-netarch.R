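# Architecture contracts: shapes, determinism, regularization placement,
# nesting structure, freezing, and checkpoint round-trips.

ns <- asNamespace("rnascopeseg")

tiny_cfg <- function(...) {
  network_config("tiny", backbone_droppath = 0, upscale_dropout = 0,
                 final_section_mode = "none", ...)
}

test_that("configuration validation rejects bad inputs", {
  expect_error(network_config("giant"), "backbone_size")
  expect_error(network_config(input_size = 100), "divisible by 32")
  cfg <- network_config()
  expect_equal(cfg$backbone_size, "base")
  expect_equal(cfg$output_channels, 1L)
})

test_that("blocks preserve shape and are deterministic without regularization", {
  set.seed(1)
  x <- array(rnorm(6 * 8 * 8 * 2), dim = c(6, 8, 8, 2))
  for (blk in list(build_convnext_block(6, 0), build_upscale_block(6, 0))) {
    y1 <- blk$fwd(x, training = TRUE)
    expect_equal(dim(y1), dim(x))
    # inference after a training pass (running stats populated)
    y2 <- blk$fwd(x, training = FALSE)
    y3 <- blk$fwd(x, training = FALSE)
    expect_identical(y2, y3)
  }
  # all-zero input gives an identical bias response across calls
  blk <- build_convnext_block(6, 0)
  z <- array(0, dim = c(6, 8, 8, 2))
  expect_identical(blk$fwd(z, FALSE), blk$fwd(z, FALSE))
})

test_that("custom upscaling block has the documented layer inventory", {
  inv_up <- ns$layer_inventory(build_upscale_block(8, 0.15))
  inv_cn <- ns$layer_inventory(build_convnext_block(8, 0.1))
  # ConvNeXt block: layer norm + DropPath, no dropout, no batch norm
  expect_equal(inv_cn, c("dwconv", "layernorm", "pwconv", "gelu", "pwconv",
                         "layerscale", "droppath"))
  # custom block: batch norm twice (branch + skip), DropOut before the skip
  # join, trailing activation, and no DropPath / layer norm anywhere
  expect_equal(inv_up, c("dwconv", "batchnorm", "pwconv", "gelu", "pwconv",
                         "layerscale", "dropout", "batchnorm", "gelu"))
  branch <- inv_up[1:7]
  expect_equal(branch[length(branch)], "dropout")
  expect_false("droppath" %in% inv_up)
  expect_false("dropout" %in% inv_cn)
})

test_that("backbone endpoints halve in resolution from 1/4 to 1/32", {
  set.seed(2)
  bb <- build_backbone(tiny_cfg(input_size = 224))
  x <- array(rnorm(3 * 224 * 224), dim = c(3, 224, 224, 1))
  e <- bb$fwd(x)
  expect_equal(vapply(e, function(t) dim(t)[2], numeric(1)), c(56, 28, 14, 7))
  bb64 <- build_backbone(tiny_cfg(input_size = 64))
  e64 <- bb64$fwd(array(rnorm(3 * 64 * 64), dim = c(3, 64, 64, 1)))
  expect_equal(vapply(e64, function(t) dim(t)[2], numeric(1)), c(16, 8, 4, 2))
  expect_equal(vapply(e64, function(t) dim(t)[1], numeric(1)),
               c(32, 64, 128, 256))
})

test_that("droppath lives only in the backbone, dropout only in the decoder", {
  cfg <- network_config("tiny", backbone_droppath = 0.2, upscale_dropout = 0.15,
                        final_section_mode = "none", input_size = 64)
  m <- build_network(cfg, seed = 1)
  bb_layers <- ns$collect_layers(m$backbone)
  dec_layers <- ns$collect_layers(m$decoder)
  bb_dp <- Filter(function(l) l$kind == "droppath", bb_layers)
  expect_gt(max(vapply(bb_dp, function(l) l$rate, numeric(1))), 0)
  expect_false("dropout" %in% vapply(bb_layers, `[[`, character(1), "kind"))
  dec_do <- Filter(function(l) l$kind == "dropout", dec_layers)
  expect_true(all(vapply(dec_do, function(l) l$rate, numeric(1)) == 0.15))
  expect_true(all(vapply(Filter(function(l) l$kind == "droppath", dec_layers),
                         function(l) l$rate, numeric(1)) == 0))
  # final section with mode "none": no active stochastic layer
  fin_layers <- ns$collect_layers(m$final)
  kinds <- vapply(fin_layers, `[[`, character(1), "kind")
  rates <- vapply(fin_layers, function(l) l$rate %||% 0, numeric(1))
  expect_true(all(rates[kinds %in% c("dropout", "droppath")] == 0))
})

test_that("nested decoder has the U-net++ triangular node count and output size", {
  cfg <- tiny_cfg(input_size = 64)
  m <- build_network(cfg, seed = 3)
  expect_equal(m$decoder$node_count, 6)
  x <- array(rnorm(3 * 64 * 64), dim = c(3, 64, 64, 1))
  e <- m$backbone$fwd(x)
  h <- m$decoder$fwd(e)
  expect_equal(dim(h)[2:3], c(16, 16))   # 1/4 of a 64 input
  # endpoint resolution mismatch is rejected
  e_bad <- e
  e_bad[[2]] <- e[[3]]
  expect_error(m$decoder$fwd(e_bad), "halving")
})

test_that("full network maps HxWx3 to HxW probabilities for any /32 size", {
  set.seed(4)
  m <- build_network(tiny_cfg(input_size = 64), seed = 4)
  for (size in c(32, 64)) {
    x <- array(rnorm(3 * size * size * 2), dim = c(3, size, size, 2))
    y <- ns$model_forward(m, x)
    expect_equal(dim(y), c(1, size, size, 2))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_error(ns$model_forward(m, array(0, dim = c(3, 48, 48, 1))),
               "divisible by 32")
  # repeated inference passes are bit-identical
  x <- array(rnorm(3 * 32 * 32), dim = c(3, 32, 32, 1))
  expect_identical(ns$model_forward(m, x), ns$model_forward(m, x))
})

test_that("freezing locks every backbone parameter through an optimizer step", {
  set.seed(5)
  m <- build_network(tiny_cfg(input_size = 32), seed = 5)
  freeze_backbone(m, TRUE)
  cp <- count_params(m)
  expect_equal(unname(cp$sections$backbone["trainable"]), 0)
  expect_gt(unname(cp$sections$decoder["trainable"]), 0)
  before <- get_weights(m, "backbone")
  dec_before <- get_weights(m, "decoder")
  x <- array(rnorm(3 * 32 * 32), dim = c(3, 32, 32, 1))
  gt <- ns$masks_to_tensor(list(render_gt_mask(data.frame(x = 5, y = 5),
                                               c(32, 32))))
  y <- ns$model_forward(m, x, training = TRUE)
  ns$model_backward(m, ns$loss_grad(loss_config("tversky"), y, gt))
  ns$adadelta_step(ns$model_layers(m), ns$adadelta_state(), optimizer_config())
  after <- get_weights(m, "backbone")
  expect_identical(before, after)
  dec_after <- get_weights(m, "decoder")
  expect_false(identical(dec_before, dec_after))
})

test_that("backbone weight loading round-trips and validates shapes", {
  set.seed(6)
  m1 <- build_network(tiny_cfg(input_size = 32), seed = 6)
  m2 <- build_network(tiny_cfg(input_size = 32), seed = 7)
  x <- array(rnorm(3 * 32 * 32), dim = c(3, 32, 32, 1))
  expect_false(identical(ns$model_forward(m1, x), ns$model_forward(m2, x)))
  load_backbone_weights(m2, get_weights(m1, "backbone"))
  e1 <- m1$backbone$fwd(x)
  e2 <- m2$backbone$fwd(x)
  expect_equal(e1, e2)
  expect_message(load_backbone_weights(m1, NULL), "random initialization")
  # a shape-incompatible source is rejected with the offending tensor named
  bad <- get_weights(m1, "backbone")
  bad[[1]]$W <- array(0, dim = c(2, 2))
  expect_error(load_backbone_weights(m2, bad), "shape mismatch")
  # and a truncated source is rejected outright
  expect_error(load_backbone_weights(m2, bad[1:3]), "length mismatch")
})

test_that("checkpoints reproduce the forward pass bit-exactly", {
  set.seed(8)
  m <- build_network(tiny_cfg(input_size = 32), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- array(rnorm(3 * 32 * 32), dim = c(3, 32, 32, 1))
  expect_identical(ns$model_forward(m, x), ns$model_forward(m2, x))
  unlink(path)
})
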