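# Cross-organ inference: evaluate every trained model on every organ's
# held-out test split, assemble the accuracy/AUC/F1 matrix, flag similar
# organ pairs by the accuracy > 0.9 criterion, and quantify
# cancer-vs-normal separability of model embeddings.

#' Evaluate a classifier on a labelled test set
#'
#' Accuracy at argmax, F1 for the cancer-positive class, and rank-based
#' AUC from the cancer-class probability (tied scores counted 1/2).
#'
#' @param model a `patch_classifier`.
#' @param test_set a `patch_dataset` (its `test` split is used) or a list
#'   of patches plus `labels`.
#' @param labels class labels ("cancer"/"normal") when `test_set` is a
#'   plain list of patches.
#' @param split which dataset split to evaluate (default "test").
#' @return list with `accuracy`, `auc`, `f1`, `n`, and the per-patch
#'   cancer probabilities.
#' @export
evaluate_classifier <- function(model, test_set, labels = NULL,
                                split = "test") {
  stopifnot(inherits(model, "patch_classifier"))
  if (inherits(test_set, "patch_dataset")) {
    idx <- which(test_set$meta$split == split)
    patches <- test_set$records[idx]
    labels <- test_set$meta$class[idx]
  } else patches <- test_set
  stopifnot(length(labels) == length(patches))
  y <- as.integer(labels == "cancer")
  prob <- predict(model, patches, type = "prob")[, "cancer"]
  pred <- as.integer(prob >= 0.5)
  accuracy <- mean(pred == y)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(y)) < 2L) {
    warning("single-class test set: AUC undefined")
    NA_real_
  } else auc_rank(prob, y)
  list(accuracy = accuracy, auc = auc, f1 = f1, n = length(y),
       cancer_prob = prob, labels = y)
}

# Rank-based AUC (Mann-Whitney): ties get rank midpoints, equivalent to
# counting tied positive/negative pairs as 1/2.
auc_rank <- function(scores, y) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-organ inference matrix
#'
#' Evaluates each organ's model on each organ's held-out test split.
#' Rows index the model's training organ; columns index the test organ;
#' the diagonal is self-organ performance.
#'
#' @param models named list of `patch_classifier`s (names = organ ids).
#' @param datasets named list of `patch_dataset`s with matching names.
#' @param split dataset split used for testing (default "test",
#'   the 10% held-out split).
#' @return an object of class `cross_matrix`: list of `accuracy`, `auc`,
#'   `f1` matrices, `n_test` counts, and the organ order.
#' @export
cross_matrix <- function(models, datasets, split = "test") {
  organs <- names(models)
  stopifnot(!is.null(organs), all(organs %in% names(datasets)))
  m <- matrix(NA_real_, length(organs), length(organs),
              dimnames = list(model = organs, test = organs))
  acc <- auc <- f1 <- m
  n_test <- stats::setNames(integer(length(organs)), organs)
  for (j in seq_along(organs)) {
    ds <- datasets[[organs[j]]]
    if (is.null(ds)) { warning("missing dataset for organ ", organs[j]); next }
    n_test[j] <- sum(ds$meta$split == split)
    for (i in seq_along(organs)) {
      ev <- evaluate_classifier(models[[organs[i]]], ds, split = split)
      acc[i, j] <- ev$accuracy; auc[i, j] <- ev$auc; f1[i, j] <- ev$f1
    }
  }
  structure(list(organs = organs, accuracy = acc, auc = auc, f1 = f1,
                 n_test = n_test),
            class = "cross_matrix")
}

#' @export
print.cross_matrix <- function(x, ...) {
  cat("Cross-organ inference accuracy (rows = model organ):\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' Plot a cross-inference matrix as a heatmap
#' @param x a `cross_matrix`.
#' @param metric `"accuracy"`, `"auc"` or `"f1"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cross_matrix <- function(x, metric = "accuracy", ...) {
  m <- x[[metric]]
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "test organ",
                  ylab = "model organ",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_len(n), colnames(m))
  graphics::axis(2, seq_len(n), rev(rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n - i + 1, sprintf("%.2f", m[i, j]), cex = 0.8)
  invisible(x)
}

#' Serialize a cross matrix to TSV
#'
#' Fixed organ order and fixed numeric formatting, so identical inputs
#' produce byte-identical files.
#' @param x a `cross_matrix`.
#' @param path output file; one block per metric.
#' @export
write_cross_matrix <- function(x, path) {
  con <- file(path, "wb")  # binary mode: fixed \n endings
  on.exit(close(con))
  for (metric in c("accuracy", "auc", "f1")) {
    writeLines(paste0("# ", metric), con)
    writeChar(format_tsv_matrix(x[[metric]]), con, eos = NULL)
  }
  invisible(path)
}

#' Flag similar organ pairs from a cross matrix
#'
#' An ordered pair (model organ -> test organ) is similar when its
#' cross-inference accuracy exceeds the threshold.  Flags are not forced
#' symmetric: A -> B may qualify while B -> A does not.
#'
#' @param x a `cross_matrix`.
#' @param threshold accuracy threshold (default 0.9).
#' @param include_diagonal include self-organ cells (default FALSE).
#' @return data.frame with `model_organ`, `test_organ`, `accuracy`,
#'   `similar`.
#' @export
flag_similar <- function(x, threshold = 0.9, include_diagonal = FALSE) {
  stopifnot(inherits(x, "cross_matrix"))
  out <- NULL
  for (i in seq_along(x$organs)) for (j in seq_along(x$organs)) {
    if (!include_diagonal && i == j) next
    out <- rbind(out, data.frame(model_organ = x$organs[i],
                                 test_organ = x$organs[j],
                                 accuracy = x$accuracy[i, j],
                                 similar = isTRUE(x$accuracy[i, j] > threshold)))
  }
  out
}

# ---- embeddings and separability ------------------------------------------

#' Embed patches and project to 2-D
#'
#' Embeddings are the pooled activations of the backbone's final
#' convolutional stage (the layer feeding the fully connected head).
#' The 2-D view is a t-distributed stochastic neighbor embedding; the
#' separability score is leave-one-out 1-nearest-neighbor accuracy in the
#' ORIGINAL embedding space, so it does not depend on the stochastic
#' projection.
#'
#' @param model a `patch_classifier`.
#' @param patches list of patches or a `patch_dataset`.
#' @param labels class labels (taken from the dataset when omitted).
#' @param perplexity t-SNE perplexity (default 30; needs at least
#'   `3 * perplexity + 1` samples).
#' @param seed seed for the projection.
#' @return list with `coords` (n x 2), `embedding` (n x d),
#'   `separability`, `labels`, `perplexity`.
#' @export
embed_and_project <- function(model, patches, labels = NULL,
                              perplexity = 30, seed = 1L) {
  if (inherits(patches, "patch_dataset")) {
    labels <- patches$meta$class
    patches <- patches$records
  }
  n <- length(patches)
  if (n < 20L) stop("need at least 20 patches to embed")
  stopifnot(length(labels) == n)
  need <- 3 * perplexity + 1
  if (n < need)
    stop(sprintf("perplexity %g needs at least %d samples (have %d)",
                 perplexity, ceiling(need), n))
  emb <- predict(model, patches, type = "embedding")
  coords <- tsne_project(emb, perplexity = perplexity, seed = seed)
  list(coords = coords, embedding = emb,
       separability = knn1_loo_accuracy(emb, labels),
       labels = labels, perplexity = perplexity)
}

#' Leave-one-out 1-nearest-neighbor label accuracy
#' @param x n x d numeric matrix.
#' @param labels length-n labels.
#' @return fraction of points whose nearest other point shares their label.
#' @export
knn1_loo_accuracy <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  mean(labels[nn] == labels)
}

#' t-SNE projection to 2-D
#'
#' Standard exact t-SNE: per-point Gaussian bandwidths calibrated to the
#' target perplexity by bisection, symmetrized input affinities, Student-t
#' low-dimensional kernel, gradient descent with momentum and early
#' exaggeration.  Suited to the data sizes this package handles (up to a
#' few thousand points).
#'
#' @param x n x d matrix.
#' @param perplexity effective neighbor count.
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the initial layout.
#' @return n x 2 coordinate matrix.
#' @export
tsne_project <- function(x, perplexity = 30, n_iter = 400L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  D2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { H <- 0; p[] <- 0 }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2))
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    mult <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    inc <- mom * inc - 200 * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
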