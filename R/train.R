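# Training of per-organ cancer-vs-normal patch classifiers: weighted
# cross-entropy loss, class-stratified batches, flip/crop augmentation,
# per-channel normalization computed on the training split, and
# best-validation-accuracy checkpointing.

#' Weighted cross-entropy loss
#'
#' Mean over samples of `w[y] * (-log softmax(logits)[y])`, normalized by
#' the sum of the applied weights (so weights act as per-class sample
#' multiplicities).
#'
#' @param logits numeric matrix, samples in rows, 2 columns.
#' @param labels integer class indices in {0, 1} (0 = normal, 1 = cancer).
#' @param weights positive per-class weights, length 2.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels, weights = c(1, 1)) {
  logits <- rbind(logits)
  if (!all(is.finite(logits))) stop("non-finite logits")
  stopifnot(ncol(logits) == 2L, length(labels) == nrow(logits),
            all(labels %in% c(0L, 1L)), length(weights) == 2L,
            all(weights > 0))
  mx <- pmax(logits[, 1], logits[, 2])
  lse <- mx + log(exp(logits[, 1] - mx) + exp(logits[, 2] - mx))
  ll <- logits[cbind(seq_len(nrow(logits)), labels + 1L)] - lse
  w <- weights[labels + 1L]
  sum(-w * ll) / sum(w)
}

#' Training configuration
#'
#' @param optimizer `"adam"`, `"rmsprop"` or `"sgd"`.
#' @param learning_rate positive step size.
#' @param batch_size samples per batch (the full-scale convention is 256;
#'   the default here suits desk-scale datasets).
#' @param epochs training epochs.
#' @param class_weights per-class loss weights, or NULL for inverse class
#'   frequency on the training split (normalized to mean 1).
#' @param augment_flip,augment_crop enable random horizontal flip and
#'   random crop (crop to `crop_fraction` of the side, resized back).
#' @param crop_fraction crop side as a fraction of the patch side.
#' @param lr_decay_factor multiplier applied to the learning rate for the
#'   final third of the epochs (1 = constant rate); the lowered-rate
#'   phase settles the weights so held-out probabilities saturate.
#' @param seed master seed fanning out to initialization, batch order and
#'   augmentation.
#' @param init_seed separate seed for weight initialization, or NULL to
#'   derive it from `seed`.  Training several models from one shared
#'   initialization (the usual role of a common pretrained backbone)
#'   makes their attention maps comparable.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "rmsprop", "sgd"),
                         learning_rate = 3e-3,
                         batch_size = 32L,
                         epochs = 10L,
                         class_weights = NULL,
                         augment_flip = TRUE,
                         augment_crop = TRUE,
                         crop_fraction = 0.9,
                         lr_decay_factor = 0.2,
                         seed = 1L,
                         init_seed = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            is.null(class_weights) || all(class_weights > 0),
            crop_fraction > 0, crop_fraction <= 1,
            lr_decay_factor > 0, lr_decay_factor <= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weights = class_weights,
                 augment_flip = augment_flip, augment_crop = augment_crop,
                 crop_fraction = crop_fraction,
                 lr_decay_factor = lr_decay_factor,
                 seed = as.integer(seed),
                 init_seed = if (!is.null(init_seed)) as.integer(init_seed)),
            class = "train_config")
}

#' Class-stratified batches for one epoch
#'
#' Every batch preserves the class ratio within one sample; every sample
#' is used exactly once per epoch; deterministic given the seed.
#'
#' @param labels vector of class labels (factor/character/integer), or a
#'   `patch_dataset` whose training split is used.
#' @param batch_size samples per batch.
#' @param seed integer seed.
#' @return list of integer index vectors (into `labels`).
#' @export
stratified_batches <- function(labels, batch_size, seed = 1L) {
  if (inherits(labels, "patch_dataset")) {
    idx <- which(labels$meta$split == "train")
    lab <- labels$meta$class[idx]
    batches <- stratified_batches(lab, batch_size, seed)
    return(lapply(batches, function(b) idx[b]))
  }
  lab <- as.character(labels)
  classes <- sort(unique(lab))
  if (length(classes) < 2L)
    stop("stratified batching needs both classes present")
  n <- length(lab)
  n_batches <- ceiling(n / batch_size)
  with_seed(seed, {
    per_batch <- vector("list", n_batches)
    for (cl in classes) {
      pos <- sample(which(lab == cl))
      # largest-remainder allocation of this class across batches
      quota <- diff(floor(seq(0, length(pos), length.out = n_batches + 1)))
      start <- cumsum(c(0, quota))
      for (b in seq_len(n_batches))
        per_batch[[b]] <- c(per_batch[[b]],
                            pos[(start[b] + 1):start[b + 1]][seq_len(quota[b])])
    }
    lapply(per_batch, sample)
  })
}

# Random horizontal flip + random crop on a (H, W, C, N) batch.  Consumes
# the current RNG stream (seeded by the caller).
augment_batch <- function(x, flip = TRUE, crop = TRUE, crop_fraction = 0.9) {
  d <- dim(x)
  n <- d[4]
  if (flip) {
    do_flip <- stats::runif(n) < 0.5
    for (i in which(do_flip)) x[, , , i] <- x[, rev(seq_len(d[2])), , i]
  }
  if (crop && crop_fraction < 1) {
    side <- max(8L, round(crop_fraction * d[1]))
    for (i in seq_len(n)) {
      r0 <- sample.int(d[1] - side + 1L, 1L)
      c0 <- sample.int(d[2] - side + 1L, 1L)
      sub <- x[r0:(r0 + side - 1L), c0:(c0 + side - 1L), , i, drop = FALSE]
      x[, , , i] <- resize_bilinear(array(sub, dim(sub)[1:3]), d[1], d[2])
    }
  }
  x
}

#' Train a cancer-vs-normal patch classifier
#'
#' Fits the network on the dataset's training split, monitors the
#' validation split each epoch, and returns the checkpoint with the best
#' validation accuracy.  All randomness (weight init, batch order,
#' augmentation, dropout) derives from `config$seed`.
#'
#' @param dataset a `patch_dataset` with non-empty train and val splits.
#' @param spec a `model_spec`.
#' @param config a `train_config`.
#' @return an object of class `patch_classifier`: the fitted network,
#'   normalization statistics, per-epoch history, and provenance.
#' @export
fit_patch_classifier <- function(dataset, spec = model_spec(),
                                 config = train_config()) {
  stopifnot(inherits(dataset, "patch_dataset"),
            inherits(spec, "model_spec"), inherits(config, "train_config"))
  tr_idx <- which(dataset$meta$split == "train")
  va_idx <- which(dataset$meta$split == "val")
  if (!length(tr_idx) || !length(va_idx))
    stop("dataset must have non-empty train and val splits")
  organ <- dataset$meta$organ[1]

  norm_stats <- channel_stats(dataset$records[tr_idx])
  y_all <- as.integer(dataset$meta$class == "cancer")
  class_weights <- config$class_weights
  if (is.null(class_weights)) {
    freq <- c(mean(y_all[tr_idx] == 0L), mean(y_all[tr_idx] == 1L))
    class_weights <- (1 / freq) / mean(1 / freq)
  }

  init_seed <- if (!is.null(config$init_seed)) config$init_seed
               else derive_seed(config$seed, "init")
  net <- build_model(spec, seed = init_seed)
  xva <- as_image_batch(dataset$records[va_idx], norm_stats)
  yva <- y_all[va_idx]

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(params = nn_params(net), val_acc = -Inf, epoch = 0L,
               bn = net)
  if (config$epochs > 0L) {
    opt <- make_optimizer(config$optimizer, config$learning_rate)
    decay_from <- ceiling(config$epochs * 2 / 3) + 1L
    for (ep in seq_len(config$epochs)) {
      lr_scale <- if (ep >= decay_from) config$lr_decay_factor else 1
      batches <- stratified_batches(dataset$meta$class[tr_idx],
                                    config$batch_size,
                                    seed = derive_seed(config$seed,
                                                       paste0("batches", ep)))
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      aug_seed <- derive_seed(config$seed, paste0("aug", ep))
      with_seed(aug_seed, {
        for (b in batches) {
          idx <- tr_idx[b]
          x <- as_image_batch(dataset$records[idx], norm_stats)
          x <- augment_batch(x, config$augment_flip, config$augment_crop,
                             config$crop_fraction)
          y <- y_all[idx]
          fw <- nn_forward(net, x, train = TRUE, want_cache = TRUE)
          logits <- t(fw$logits)                       # N x 2
          loss <- weighted_cross_entropy(logits, y, class_weights)
          if (!is.finite(loss))
            stop(sprintf(paste0("training diverged (non-finite loss) at ",
                                "epoch %d; lr = %g, optimizer = %s"),
                         ep, config$learning_rate, config$optimizer))
          p <- softmax_rows(logits)
          w <- class_weights[y + 1L]
          dlog <- (p - cbind(1 - y, y)) * w / sum(w)   # N x 2
          bk <- nn_backward(net, fw$caches, t(dlog))
          net <- nn_update_bn(net, fw$caches)
          g <- nn_flatten_grads(net, bk$grads)
          net <- nn_set_params(net, opt$step(nn_params(net), g, lr_scale))
          ep_loss <- ep_loss + loss * length(y)
          ep_n <- ep_n + length(y)
          ep_correct <- ep_correct + sum(max.col(logits, "first") - 1L == y)
        }
      })
      va <- .eval_logits(net, xva)
      val_loss <- weighted_cross_entropy(va, yva, class_weights)
      val_acc <- mean(max.col(va, "first") - 1L == yva)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / ep_n, train_acc = ep_correct / ep_n,
        val_loss = val_loss, val_acc = val_acc))
      # ties go to the later epoch: equal validation accuracy, more
      # optimization of the training loss (better-calibrated checkpoint)
      if (val_acc >= best$val_acc) {
        best <- list(params = nn_params(net), val_acc = val_acc, epoch = ep,
                     bn = net)
      }
    }
    net <- nn_set_params(best$bn, best$params)
  }

  structure(list(net = net, spec = spec, config = config,
                 norm_stats = norm_stats, class_weights = class_weights,
                 organ = organ, history = history,
                 best_epoch = best$epoch, best_val_acc = best$val_acc),
            class = "patch_classifier")
}

.eval_logits <- function(net, x, batch = 64L) {
  n <- dim(x)[4]
  out <- matrix(0, n, 2L)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    fw <- nn_forward(net, x[, , , s:e, drop = FALSE], train = FALSE)
    out[s:e, ] <- t(fw$logits)
  }
  out
}

softmax_rows <- function(logits) {
  mx <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - mx); e2 <- exp(logits[, 2] - mx)
  cbind(e1, e2) / (e1 + e2)
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("Patch classifier for organ:", x$organ, "\n")
  print(x$net)
  if (nrow(x$history))
    cat(sprintf("  best val accuracy %.3f at epoch %d/%d\n",
                x$best_val_acc, x$best_epoch, nrow(x$history)))
  else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.patch_classifier <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Plot training history
#' @param x a `patch_classifier`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.patch_classifier <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { message("no history to plot (0 epochs)"); return(invisible(x)) }
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "b",
                    pch = c(1, 19), lty = 1, xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"),
                   pch = c(1, 19), lty = 1, col = 1:2, bty = "n")
  invisible(x)
}

#' Predict from a patch classifier
#'
#' @param object a `patch_classifier`.
#' @param newdata a `patch_dataset`, list of patches/`patch_record`s, a
#'   single H x W x 3 array, or a prepared (H, W, 3, N) batch.
#' @param type `"prob"` (per-class softmax probabilities), `"class"`
#'   (labels), `"logits"`, or `"embedding"` (pooled backbone features).
#' @param ... unused.
#' @return matrix of probabilities/logits/embeddings, or character vector
#'   of classes.
#' @export
predict.patch_classifier <- function(object, newdata,
                                     type = c("prob", "class", "logits",
                                              "embedding"), ...) {
  type <- match.arg(type)
  x <- if (is.array(newdata) && length(dim(newdata)) == 4L) newdata
       else if (inherits(newdata, "patch_dataset"))
         as_image_batch(newdata$records, object$norm_stats)
       else as_image_batch(newdata, object$norm_stats)
  if (type == "embedding") {
    n <- dim(x)[4]; emb <- NULL
    for (s in seq(1L, n, by = 64L)) {
      e <- min(s + 63L, n)
      fw <- nn_forward(object$net, x[, , , s:e, drop = FALSE],
                       collect = object$net$embed_layer)
      emb <- rbind(emb, t(fw$collected[[object$net$embed_layer]]))
    }
    return(emb)
  }
  logits <- .eval_logits(object$net, x)
  colnames(logits) <- c("normal", "cancer")
  switch(type,
         logits = logits,
         prob = { p <- softmax_rows(logits); colnames(p) <- c("normal", "cancer"); p },
         class = c("normal", "cancer")[max.col(logits, "first")])
}
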