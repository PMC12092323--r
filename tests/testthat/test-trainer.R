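# Training components: losses and their identities, ground-truth masks,
# augmentation, normalization, subdivision, the curriculum, and seeded
# training behaviour.

ns <- asNamespace("rnascopeseg")

test_that("ground-truth crosses have 5 pixels, clipped at borders", {
  m <- render_gt_mask(data.frame(x = 10, y = 12), c(32, 32))
  expect_equal(sum(m), 5)
  expect_equal(m[13, 11], 1)            # centre (0-based 10,12)
  expect_equal(m[12, 11] + m[14, 11] + m[13, 10] + m[13, 12], 4)
  corner <- render_gt_mask(data.frame(x = 0, y = 0), c(16, 16))
  expect_equal(sum(corner), 3)
  expect_equal(sum(render_gt_mask(data.frame(x = integer(0), y = integer(0)),
                                  c(8, 8))), 0)
  # overlapping crosses take the union
  two <- render_gt_mask(data.frame(x = c(5, 6), y = c(5, 5)), c(16, 16))
  expect_equal(sum(two), 8)
  expect_error(render_gt_mask(data.frame(x = 20, y = 2), c(16, 16)), "outside")
})

test_that("tversky loss reproduces hand-computed cases", {
  pred <- matrix(c(1, 0, 0, 0), 2, 2)
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  # TP 1, FN 1, FP 0, alpha 0.6, s = 0: 1 - 1/1.6
  expect_equal(tversky_loss(pred, gt, alpha = 0.6, smooth = 0),
               1 - 1 / 1.6, tolerance = 1e-12)
  expect_lt(tversky_loss(gt, gt, alpha = 0.6), 1e-6)
  expect_gt(tversky_loss(1 - gt, gt, alpha = 0.6, smooth = 1e-9), 1 - 1e-6)
  expect_error(tversky_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("dice is tversky at alpha 0.5 and jaccard dominates dice", {
  set.seed(10)
  for (i in 1:100) {
    pred <- matrix(runif(64), 8, 8)
    gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_lt(abs(tversky_loss(pred, gt, alpha = 0.5) - dice_loss(pred, gt)),
              1e-6)
    expect_gte(jaccard_loss(pred, gt) + 1e-12, dice_loss(pred, gt))
  }
  gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_lt(dice_loss(gt, gt), 1e-6)
  expect_lt(jaccard_loss(gt, gt), 1e-6)
  expect_lt(bce_loss(gt, gt), 1e-5)
  # all-negative gt with all-zero pred: smoothing convention gives loss 0
  z <- matrix(0, 8, 8)
  expect_equal(dice_loss(z, z), 0)
})

test_that("corrupting a perfect prediction raises tversky loss monotonically", {
  set.seed(4)
  gt <- matrix(0, 16, 16)
  gt[sample(256, 20)] <- 1
  pos <- which(gt == 1)
  losses <- vapply(0:6, function(k) {
    pred <- gt
    if (k > 0) pred[pos[seq_len(k)]] <- 0
    tversky_loss(pred, gt, alpha = 0.6)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("imagenet normalization centres the mean colour and round-trips", {
  mean_bgr <- rev(c(0.485, 0.456, 0.406)) * 255
  img <- array(rep(mean_bgr, each = 16), dim = c(4, 4, 3))
  out <- normalize_input(img)
  expect_lt(max(abs(out)), 1e-6)
  set.seed(2)
  img2 <- array(sample(0:255, 48, replace = TRUE), dim = c(4, 4, 3))
  expect_equal(denormalize_input(normalize_input(img2)), img2,
               tolerance = 1e-10)
  expect_true(all(is.finite(normalize_input(img2))))
})

test_that("augmentation transforms image and mask jointly", {
  set.seed(6)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  mask <- render_gt_mask(data.frame(x = c(8, 20), y = c(10, 25)), c(32, 32))
  # flips alone conserve the positive pixel count
  cfgf <- augment_config(max_rotation_degrees = 0)
  for (i in 1:10) {
    au <- augment(img, mask, cfgf)
    expect_equal(sum(au$mask), sum(mask))
    expect_true(all(au$mask %in% c(0, 1)))
  }
  # same RNG state implies the same transform for both outputs
  set.seed(9); a1 <- augment(img, mask)
  set.seed(9); a2 <- augment(img, mask)
  expect_identical(a1, a2)
  # double horizontal flip is the identity
  flipped <- img[, rev(seq_len(32)), , drop = FALSE]
  expect_identical(flipped[, rev(seq_len(32)), , drop = FALSE], img)
  # rotation keeps masks binary
  au <- augment(img, mask, augment_config(max_rotation_degrees = 90))
  expect_true(all(au$mask %in% c(0, 1)))
})

test_that("subdivision grids a 480 patch as 3x3 stride-128 tiles", {
  img <- array(runif(480 * 480 * 3), dim = c(480, 480, 3))
  dots <- data.frame(x = c(230, 10), y = c(230, 470))
  tiles <- subdivide_patch(img, dots, mode = "eval")
  expect_equal(length(tiles), 9)
  org <- t(vapply(tiles, `[[`, numeric(2), "origin"))
  expect_setequal(unique(org[, 1]), c(0, 128, 256))
  expect_setequal(unique(org[, 2]), c(0, 128, 256))
  centre <- tiles[[which(org[, 1] == 128 & org[, 2] == 128)]]
  expect_true(any(centre$dots$x == 102 & centre$dots$y == 102))
  # train mode crops are seed-reproducible
  set.seed(3); t1 <- subdivide_patch(img, dots, mode = "train", n_crops = 2)
  set.seed(3); t2 <- subdivide_patch(img, dots, mode = "train", n_crops = 2)
  expect_identical(lapply(t1, `[[`, "origin"), lapply(t2, `[[`, "origin"))
  expect_error(subdivide_patch(array(0, c(100, 100, 3))), "smaller")
})

test_that("the default curriculum matches the published six phases", {
  s <- default_schedule()
  expect_length(s, 6)
  expect_equal(vapply(s, `[[`, integer(1), "real"), rep(460L, 6))
  expect_equal(vapply(s, `[[`, integer(1), "generated"),
               c(1071L, 460L, 230L, 115L, 58L, 0L))
  expect_equal(vapply(s, `[[`, integer(1), "epochs"),
               c(rep(128L, 5), 1024L))
  expect_equal(vapply(s, `[[`, logical(1), "backbone_frozen"),
               c(TRUE, rep(FALSE, 5)))
  expect_equal(sum(vapply(s, `[[`, integer(1), "epochs")), 1664L)
})

test_that("training smoke: finite history, frozen backbone, reproducibility", {
  set.seed(20)
  data <- make_synthetic_samples(301:304, c(64, 64))
  cfg <- network_config("tiny", backbone_droppath = 0, upscale_dropout = 0,
                        final_section_mode = "none", input_size = 64)
  sched <- list(phase_spec(4, 0, 1, backbone_frozen = TRUE))
  m <- build_network(cfg, seed = 31)
  bb_before <- get_weights(m, "backbone")
  m <- train(m, data, schedule = sched, seed = 5, augment_cfg = NULL)
  h <- attr(m, "history")
  expect_equal(nrow(h), 1)
  expect_true(is.finite(h$loss))
  expect_identical(get_weights(m, "backbone"), bb_before)
  # identical seeds give identical loss curves
  sched2 <- list(phase_spec(4, 0, 2))
  m1 <- build_network(cfg, seed = 31)
  m1 <- train(m1, data, schedule = sched2, seed = 5, augment_cfg = NULL)
  m2 <- build_network(cfg, seed = 31)
  m2 <- train(m2, data, schedule = sched2, seed = 5, augment_cfg = NULL)
  expect_identical(attr(m1, "history")$loss, attr(m2, "history")$loss)
  # a phase demanding more generated data than exists is a scheduling error
  expect_error(train(build_network(cfg, seed = 1), data,
                     schedule = list(phase_spec(4, 10, 1)), seed = 1),
               "generated")
})
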