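# Loss, batching, model construction, gradient correctness, training on
# constructed fixtures, and the hyperparameter search contract.

test_that("weighted cross entropy matches closed forms and an oracle", {
  expect_lt(weighted_cross_entropy(matrix(c(1000, -1000), 1), 0L), 1e-12)
  expect_equal(weighted_cross_entropy(matrix(c(0, 0), 1), 0L), log(2))

  two <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(weighted_cross_entropy(two, c(0L, 0L), c(2, 1)),
               brute_wce(two, c(0L, 0L), c(2, 1)), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    logits <- matrix(stats::rnorm(2 * n, 0, 3), n)
    labels <- sample(0:1, n, replace = TRUE)
    w <- stats::runif(2, 0.2, 3)
    expect_equal(weighted_cross_entropy(logits, labels, w),
                 brute_wce(logits, labels, w), tolerance = 1e-6)
  }

  expect_error(weighted_cross_entropy(matrix(c(NaN, 0), 1), 0L),
               "non-finite")
})

test_that("class weighting is equivalent to sample duplication", {
  set.seed(2)
  logits <- matrix(stats::rnorm(12), 6)
  labels <- c(0L, 0L, 0L, 0L, 1L, 1L)
  dup <- rbind(logits, logits[labels == 1L, , drop = FALSE])
  dup_labels <- c(labels, 1L, 1L)
  expect_equal(weighted_cross_entropy(logits, labels, c(1, 2)),
               weighted_cross_entropy(dup, dup_labels, c(1, 1)),
               tolerance = 1e-12)
})

test_that("stratified batches keep the class ratio and use every sample", {
  labels <- c(rep("cancer", 80), rep("normal", 20))
  batches <- stratified_batches(labels, 10, seed = 1)
  expect_length(batches, 10)
  for (b in batches) {
    expect_length(b, 10)
    expect_equal(sum(labels[b] == "cancer"), 8)
  }
  expect_setequal(unlist(batches), seq_along(labels))

  even <- rep(c("cancer", "normal"), each = 50)
  for (b in stratified_batches(even, 2, seed = 3))
    expect_equal(sum(even[b] == "cancer"), 1)

  expect_identical(stratified_batches(labels, 10, seed = 7),
                   stratified_batches(labels, 10, seed = 7))
  expect_error(stratified_batches(rep("cancer", 10), 2), "both classes")
})

test_that("model construction honours the head specification", {
  spec <- model_spec(fcn_layers = 1, fcn_widths = 4, fcn_dropouts = 0.2)
  net <- build_model(spec, seed = 1)
  fc <- net$layers[[which(layer_names(net) == "fc1")]]
  expect_equal(dim(fc$W), c(4L, spec$channels[3]))
  out <- net$layers[[which(layer_names(net) == "logits")]]
  expect_equal(dim(out$W), c(2L, 4L))

  # zeroed output layer maps anything to (0, 0) logits
  net0 <- build_model(spec, seed = 1)
  net0$layers[[which(layer_names(net0) == "logits")]]$W[] <- 0
  fw <- nn_forward(net0, array(0, c(64, 64, 3, 1)))
  expect_equal(as.vector(fw$logits), c(0, 0))

  expect_error(build_model(model_spec(pretrained = TRUE)), "pretrained")
  expect_error(model_spec(fcn_layers = 2, fcn_widths = 8), "length")
})

test_that("backpropagated gradients match finite differences", {
  # exercises conv, pool, batchnorm, residual block, dense and gap
  net <- structure(list(layers = list(
    layer_conv("c1", 1L, 2L, k = 3L),
    layer_bn("b1", 2L),
    layer_relu("r1"),
    layer_resblock("rb", 2L, 4L, stride = 2L),
    layer_gap("gap"),
    layer_dense("out", 4L, 2L)),
    spec = NULL, cam_layer = "r1", embed_layer = "gap"),
    class = "nn_net")
  set.seed(4)
  x <- array(stats::rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- c(0L, 1L)
  loss_of <- function(n) {
    fw <- nn_forward(n, x, train = TRUE, want_cache = TRUE)
    weighted_cross_entropy(t(fw$logits), y)
  }
  fw <- nn_forward(net, x, train = TRUE, want_cache = TRUE)
  p <- softmax_rows(t(fw$logits))
  dlog <- (p - cbind(1 - y, y)) / 2
  grads <- nn_flatten_grads(net, nn_backward(net, fw$caches, t(dlog))$grads)
  params <- nn_params(net)
  eps <- 1e-5
  for (key in c("c1.W", "c1.b", "b1.gamma", "b1.beta",
                "rb.conv1.W", "rb.down.W", "out.W")) {
    for (idx in seq_len(min(3, length(params[[key]])))) {
      pp <- params; pp[[key]][idx] <- pp[[key]][idx] + eps
      up <- loss_of(nn_set_params(net, pp))
      pp[[key]][idx] <- pp[[key]][idx] - 2 * eps
      dn <- loss_of(nn_set_params(net, pp))
      expect_equal(grads[[key]][idx], (up - dn) / (2 * eps),
                   tolerance = 1e-4,
                   label = paste("grad", key, idx))
    }
  }
})

test_that("training separates a bright/dark fixture and obeys the epoch contract", {
  ds <- separable_dataset(n_per_class = 30, seed = 5)
  fit <- fit_patch_classifier(ds, model_spec(channels = c(4L, 8L, 16L)),
                              train_config(epochs = 5, seed = 6))
  expect_gte(fit$best_val_acc, 0.95)
  te <- which(ds$meta$split == "test")
  pred <- predict(fit, ds$records[te], type = "class")
  expect_gte(mean(pred == ds$meta$class[te]), 0.95)

  fit0 <- fit_patch_classifier(ds, model_spec(), train_config(epochs = 0))
  expect_equal(nrow(fit0$history), 0)
  p0 <- predict(fit0, ds$records[te], type = "prob")
  expect_equal(dim(p0), c(length(te), 2L))

  # horizontal flips leave performance intact (no orientation shortcut)
  flipped <- lapply(ds$records[te], function(r) {
    img <- r$image
    img[, rev(seq_len(dim(img)[2])), ]
  })
  pf <- predict(fit, flipped, type = "class")
  expect_lte(abs(mean(pf == ds$meta$class[te]) -
                   mean(pred == ds$meta$class[te])), 0.05)
})

test_that("training recovers class structure on generated organs", {
  wins <- 0
  for (s in 1:3) {
    specs <- generate_shared_morphology_study(2, list(), base_seed = 40 + s,
                                              n_patches_per_class = 80)
    ds <- generate_organ_dataset(specs$A)
    fit <- fit_patch_classifier(ds, model_spec(),
                                train_config(epochs = 20, augment_crop = FALSE,
                                             seed = s))
    te <- which(ds$meta$split == "test")
    acc <- mean(predict(fit, ds$records[te], type = "class") ==
                  ds$meta$class[te])
    if (acc >= 0.9) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("search space sampling honours the stated distributions", {
  sp <- search_space()
  set.seed(8)
  draws <- replicate(1000, sample_search_space(sp), simplify = FALSE)
  lg <- log10(vapply(draws, `[[`, numeric(1), "learning_rate"))
  expect_gt(stats::ks.test(lg, "punif", -5, -1)$p.value, 0.01)
  dr <- unlist(lapply(draws, `[[`, "fcn_dropouts"))
  expect_true(all(dr >= 0.2 & dr <= 0.5))
  nl <- vapply(draws, `[[`, integer(1), "fcn_layers")
  expect_setequal(unique(nl), 1:3)
  wd <- unlist(lapply(draws, `[[`, "fcn_widths"))
  expect_true(all(wd >= 4 & wd <= 128))
  opt <- vapply(draws, `[[`, character(1), "optimizer")
  expect_setequal(unique(opt), c("adam", "rmsprop", "sgd"))
})

test_that("hyperparameter search returns the argmax trial with tie-breaks", {
  ds <- separable_dataset(n_per_class = 20, seed = 9)
  one <- hyperparameter_search(
    ds, search_space(n_trials = 1, epochs_per_trial = 2, final_epochs = 0),
    base_spec = model_spec(channels = c(4L, 8L, 16L)), seed = 10)
  expect_equal(one$best_trial, 1L)
  expect_equal(nrow(one$trials), 1)
  expect_s3_class(one$best_config, "train_config")
  expect_s3_class(one$best_spec, "model_spec")

  # selection is the argmax of the trial log, earliest trial on ties
  sr <- hyperparameter_search(
    ds, search_space(n_trials = 3, epochs_per_trial = 2, final_epochs = 0),
    base_spec = model_spec(channels = c(4L, 8L, 16L)),
    sampler = "random", seed = 12)
  accs <- sr$trials$val_acc
  expect_equal(sr$best_trial, which(accs == max(accs, na.rm = TRUE))[1])
  expect_equal(sr$best_config$learning_rate,
               sr$trials$learning_rate[sr$best_trial])
})

test_that("a workable learning rate beats a vanishing one on a separable fixture", {
  ds <- separable_dataset(n_per_class = 20, seed = 9)
  evals <- vapply(c(1e-2, 1e-5), function(lr) {
    f <- fit_patch_classifier(ds, model_spec(channels = c(4L, 8L, 16L)),
                              train_config(learning_rate = lr, epochs = 3,
                                           seed = 11))
    f$best_val_acc
  }, numeric(1))
  expect_gt(evals[1], evals[2])
})
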