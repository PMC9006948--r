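# GradCAM on constructed networks with hand-computable gradients, mask
# thresholding, bounding boxes, and the overlap metrics against pixel
# enumeration oracles.

# A minimal classifier whose CAM is analytically known: one conv layer
# with hand-set weights, gap, and a logits layer that reads one channel.
make_linear_cam_model <- function(conv_w = NULL, logit_w = c(0, 1)) {
  conv <- layer_conv("conv1", 1L, 2L, k = 3L)
  conv$W[] <- 0
  if (is.null(conv_w)) {
    conv$W[1, 5] <- 1   # channel 1 = identity (center tap)
    conv$W[2, 5] <- -1  # channel 2 = negated input
  } else conv$W <- conv_w
  out <- layer_dense("logits", 2L, 2L)
  out$W[] <- 0
  out$W[2, ] <- logit_w  # cancer logit reads the pooled channels
  net <- structure(list(layers = list(conv, layer_relu("relu1"),
                                      layer_gap("gap"), out),
                        spec = NULL, cam_layer = "relu1",
                        embed_layer = "gap"),
                   class = "nn_net")
  structure(list(net = net, norm_stats = NULL, organ = "TOY",
                 history = data.frame(), spec = NULL,
                 config = NULL), class = "patch_classifier")
}

gray_patch <- function(m) {
  img <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) img[, , ch] <- m
  img
}

test_that("gradcam reproduces hand-computed maps on constructed models", {
  # cancer logit = mean of channel 1 (= input); gradient w.r.t. channel 1
  # is uniform, channel 2 contributes nothing
  mono <- matrix(255, 8, 8)
  model <- make_linear_cam_model(logit_w = c(1, 0))  # cancer logit = pooled ch 1
  # single-channel input path: replicate input over RGB, conv reads ch 1
  # of the batch, so feed through a 1-channel patch via direct forward
  x <- array(1, c(8, 8, 1, 1))
  fw <- nn_forward(model$net, x, want_cache = TRUE, collect = "relu1")
  act <- fw$collected$relu1
  expect_equal(act[, , 1, 1], matrix(1, 8, 8))

  # uniform activation + positive weight -> uniform cam of 1
  cam <- local({
    bk <- nn_backward(model$net, fw$caches,
                      matrix(c(0, 1), 2, 1), upto = "relu1")
    grad <- bk$d_out
    alpha <- apply(grad[, , , 1, drop = FALSE], 3, mean)
    m <- alpha[1] * act[, , 1, 1] + alpha[2] * act[, , 2, 1]
    m <- pmax(m, 0); if (max(m) > 0) m / max(m) else m
  })
  expect_equal(cam, matrix(1, 8, 8))

  # logit independent of activations -> all-zero cam
  dead <- make_linear_cam_model(logit_w = c(0, 0))
  fw2 <- nn_forward(dead$net, x, want_cache = TRUE, collect = "relu1")
  bk2 <- nn_backward(dead$net, fw2$caches, matrix(c(0, 1), 2, 1),
                     upto = "relu1")
  alpha2 <- apply(bk2$d_out[, , , 1, drop = FALSE], 3, mean)
  expect_equal(unname(alpha2), c(0, 0))
})

test_that("gradcam highlights the informative image region", {
  # train quickly on bright-vs-dark, then check cam mass follows a
  # bright insert moved across a dark patch
  ds <- separable_dataset(n_per_class = 20, seed = 51)
  fit <- fit_patch_classifier(ds, model_spec(channels = c(4L, 8L, 16L)),
                              train_config(epochs = 4, seed = 5))
  dark <- array(80, c(64, 64, 3))
  corner_mass <- function(r0, c0) {
    img <- dark; img[r0:(r0 + 15), c0:(c0 + 15), ] <- 200
    cam <- gradcam(fit, img, target_class = "normal")
    sum(cam[r0:(r0 + 15), c0:(c0 + 15)]) / max(sum(cam), 1e-9)
  }
  expect_gt(corner_mass(1, 1), 0.2)
  expect_gt(corner_mass(45, 45), 0.2)
  expect_error(gradcam(fit, dark, layer = "nope"), "available layers")
})

test_that("threshold modes produce the documented masks", {
  zero <- matrix(0, 10, 10)
  expect_false(any(threshold_high_attention(zero, "value")))
  expect_false(any(threshold_high_attention(zero, "quantile")))
  expect_false(any(threshold_high_attention(zero, "hsv")))

  one <- matrix(1, 10, 10)
  expect_true(all(threshold_high_attention(one, "value", threshold = 0.6)))

  ramp <- matrix(seq(0, 1, length.out = 100), 10, 100, byrow = TRUE)
  m <- threshold_high_attention(ramp, "value", threshold = 0.6)
  on_cols <- which(apply(m, 2, any))
  expect_lte(abs(min(on_cols) - 61), 1)
  expect_true(all(m[, 70:100]))

  q <- threshold_high_attention(ramp, "quantile", quantile = 0.7)
  expect_equal(mean(q), 0.3, tolerance = 0.02)

  # default colormap: high attention renders green, low renders blue
  hsvm <- threshold_high_attention(ramp, "hsv")
  expect_true(all(hsvm[, 95:100]))
  expect_false(any(hsvm[, 1:40]))

  expect_error(threshold_high_attention(ramp, "hsv", hue_band = c(120, 100)),
               "empty hue band")
  expect_error(threshold_high_attention(ramp, "nonsense"))
})

test_that("bounding boxes are tight, per-contour, and deduplicated", {
  expect_equal(nrow(boxes_from_mask(matrix(FALSE, 30, 30))), 0)

  m <- matrix(FALSE, 60, 60)
  m[11:21, 31:51] <- TRUE   # rows 10-20, cols 30-50 in 0-based indexing
  b <- boxes_from_mask(m)
  expect_equal(unname(b[1, ]), c(10L, 30L, 21L, 51L))

  two <- matrix(FALSE, 40, 40)
  two[3:8, 3:8] <- TRUE
  two[20:30, 25:33] <- TRUE
  b2 <- boxes_from_mask(two)
  b2 <- b2[order(b2[, 1]), ]
  expect_equal(nrow(b2), 2)
  expect_equal(unname(b2[1, ]), c(2L, 2L, 8L, 8L))
  expect_equal(unname(b2[2, ]), c(19L, 24L, 30L, 33L))

  ring <- matrix(FALSE, 30, 30)
  ring[5:25, 5:25] <- TRUE
  ring[10:20, 10:20] <- FALSE  # hole -> inner contour nested in outer
  br <- boxes_from_mask(ring)
  expect_equal(nrow(br), 1)
  expect_equal(unname(br[1, ]), c(4L, 4L, 25L, 25L))
})

test_that("box IoU matches pixel enumeration, including the worked case", {
  a <- matrix(c(0L, 0L, 10L, 10L), 1)
  b <- matrix(c(5L, 5L, 15L, 15L), 1)
  expect_equal(iou_boxes(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(iou_boxes(a, a), 1.0)
  expect_equal(iou_boxes(a, matrix(c(20L, 20L, 30L, 30L), 1)), 0.0)

  set.seed(61)
  for (i in 1:100) {
    ba <- random_boxes(sample(1:3, 1))
    bb <- random_boxes(sample(1:3, 1))
    expect_equal(iou_boxes(ba, bb), brute_iou_boxes(ba, bb),
                 tolerance = 1e-12)
    expect_equal(iou_boxes(ba, bb), iou_boxes(bb, ba))
  }

  expect_warning(iou_boxes(matrix(c(0L, 0L, 0L, 5L), 1), a), "zero-area")
  expect_warning(
    expect_equal(iou_boxes(matrix(integer(0), 0, 4),
                           matrix(integer(0), 0, 4)), 0),
    "empty")
})

test_that("mask Jaccard matches counting, including the worked case", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE     # 100 px
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE     # 100 px, 50 shared
  expect_equal(jaccard_masks(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(jaccard_masks(a, a), 1.0)
  d <- matrix(FALSE, 20, 20); d[15:20, 15:20] <- TRUE
  expect_equal(jaccard_masks(a, d), 0.0)
  expect_warning(jaccard_masks(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
                 "empty")

  set.seed(62)
  for (i in 1:50) {
    ma <- matrix(stats::runif(400) < 0.3, 20, 20)
    mb <- matrix(stats::runif(400) < 0.3, 20, 20)
    expect_equal(jaccard_masks(ma, mb), brute_jaccard(ma, mb))
    expect_equal(jaccard_masks(ma, mb), jaccard_masks(mb, ma))
    expect_lte(jaccard_masks(ma, mb), 1)
  }
})

test_that("region partitions are disjoint and reconstruct the inputs", {
  g <- matrix(FALSE, 10, 10)
  A <- g; A[, 1:5] <- TRUE        # left half
  B <- g; B[1:5, ] <- TRUE        # top half
  p <- partition_regions(A, B)
  expect_equal(sum(p$overlap), 25)
  expect_true(all(which(p$overlap) ==
                    which(g | outer(1:10, 1:10, function(r, c)
                      r <= 5 & c <= 5))))
  expect_equal(sum(p$a_specific), 25)
  expect_equal(sum(p$b_specific), 25)

  same <- partition_regions(A, A)
  expect_identical(same$overlap, A)
  expect_false(any(same$a_specific) || any(same$b_specific))

  dis <- partition_regions(A & !B, B & !A)
  expect_false(any(dis$overlap))

  set.seed(63)
  for (i in 1:100) {
    ma <- matrix(stats::runif(100) < 0.4, 10, 10)
    mb <- matrix(stats::runif(100) < 0.4, 10, 10)
    pp <- partition_regions(ma, mb)
    expect_false(any(pp$overlap & pp$a_specific))
    expect_false(any(pp$overlap & pp$b_specific))
    expect_false(any(pp$a_specific & pp$b_specific))
    expect_identical(pp$overlap | pp$a_specific, ma)
    expect_identical(pp$overlap | pp$b_specific, mb)
  }
})

test_that("overlap reports are perfect for self-pairs and empty when gated out", {
  ds <- separable_dataset(n_per_class = 20, seed = 52)
  fit <- fit_patch_classifier(ds, model_spec(channels = c(4L, 8L, 16L)),
                              train_config(epochs = 6, seed = 6))
  te <- which(ds$meta$class == "cancer" & ds$meta$split == "test")
  rep_self <- overlap_report(fit, fit, ds$records[te], own_model = fit,
                             cancer_prob_min = 0.5)
  if (rep_self$n_qualifying > 0) {
    expect_equal(rep_self$mean_iou, 1.0)
    expect_equal(rep_self$mean_jaccard, 1.0)
  }
  expect_warning(
    empty <- overlap_report(fit, fit, ds$records[te], own_model = fit,
                            cancer_prob_min = 1.0),
    "no patches")
  expect_equal(empty$n_qualifying, 0L)
  expect_equal(nrow(empty$scores), 0)
})
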