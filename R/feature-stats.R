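# Statistical comparison of nucleus-feature distributions between the
# attention regions of two models, and the resulting morphological
# similarity verdict.  Similarity is read from NON-rejection of the
# per-feature two-sample t-test (high p-value = indistinguishable
# distributions), mirroring how attention-region morphometry is usually
# summarized; an equivalence-test option (TOST) is available for a
# statistically stricter reading.

#' Two-sample t-test
#'
#' Welch (default) or pooled-variance two-sided t-test.  Degenerate
#' inputs are resolved explicitly: zero variance in both samples with
#' equal means gives t = 0, p = 1; zero variance with unequal means
#' gives p = 0 with a warning.
#'
#' @param xs,ys numeric samples (each length >= 2, finite).
#' @param variant `"welch"` or `"pooled"`.
#' @return list with `t_statistic`, `p_value`, `df`, `variant`,
#'   `n_x`, `n_y`.
#' @export
two_sample_t <- function(xs, ys, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(xs) >= 2L, length(ys) >= 2L,
            all(is.finite(xs)), all(is.finite(ys)))
  out <- function(t, p, df) list(t_statistic = t, p_value = p, df = df,
                                 variant = variant,
                                 n_x = length(xs), n_y = length(ys))
  if (stats::sd(xs) == 0 && stats::sd(ys) == 0) {
    if (mean(xs) == mean(ys)) return(out(0, 1, NA_real_))
    warning("zero variance with unequal means: p-value degenerates to 0")
    return(out(sign(mean(xs) - mean(ys)) * Inf, 0, NA_real_))
  }
  tt <- stats::t.test(xs, ys, var.equal = (variant == "pooled"))
  out(unname(tt$statistic), tt$p.value, unname(tt$parameter))
}

#' Compare nucleus-feature distributions between two models
#'
#' For every feature, pools the per-patch region-level values of each
#' model (one value per patch per feature) and tests group A against
#' group B.  Features with fewer than two non-missing values on either
#' side are skipped and logged.
#'
#' @param table_a,table_b data.frames of per-patch feature rows for the
#'   two models (e.g. the `a_total` and `b_total` rows emitted by
#'   [region_feature_pipeline()] across patches).
#' @param alpha similarity level: a feature is flagged similar when
#'   p > alpha (default 0.05).
#' @param variant t-test variant, see [two_sample_t()].
#' @param features feature columns to compare (default the canonical 21).
#' @return an object of class `feature_comparison`: data.frame with
#'   `feature`, `display_name`, `feature_type`, `n_a`, `n_b`,
#'   `t_statistic`, `p_value`, `similar`, plus a `skipped` attribute.
#' @export
compare_feature_tables <- function(table_a, table_b, alpha = 0.05,
                                   variant = "welch",
                                   features = names(nucleus_feature_names())) {
  stopifnot(alpha > 0)
  disp <- nucleus_feature_names()
  rows <- NULL; skipped <- character(0)
  for (f in features) {
    xs <- table_a[[f]]; ys <- table_b[[f]]
    xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
    if (length(xs) < 2L || length(ys) < 2L) {
      skipped <- c(skipped, f)
      next
    }
    tt <- suppressWarnings(two_sample_t(xs, ys, variant))
    rows <- rbind(rows, data.frame(
      feature = f,
      display_name = if (f %in% names(disp)) disp[[f]] else f,
      feature_type = if (grepl("^neighbor_count", f)) "density" else "shape",
      n_a = length(xs), n_b = length(ys),
      t_statistic = tt$t_statistic, p_value = tt$p_value,
      similar = tt$p_value > alpha))
  }
  if (length(skipped))
    message("skipped features with too few finite values: ",
            paste(skipped, collapse = ", "))
  if (is.null(rows))
    rows <- data.frame(feature = character(0), display_name = character(0),
                       feature_type = character(0), n_a = integer(0),
                       n_b = integer(0), t_statistic = numeric(0),
                       p_value = numeric(0), similar = logical(0))
  structure(rows, skipped = skipped, alpha = alpha,
            class = c("feature_comparison", "data.frame"))
}

#' Morphological similarity verdict from feature comparisons
#'
#' A model pair is called morphologically similar when at least
#' `min_similar_features` features are flagged similar (p > alpha).
#' Counts are reported separately for shape and density features.
#'
#' @param comparisons a `feature_comparison`.
#' @param min_similar_features verdict threshold (default 11: the
#'   8-shape + 3-density benchmark of a known similar organ pair).
#' @return list with `similar` (logical), `n_similar`, `n_similar_shape`,
#'   `n_similar_density`, `n_tested`.
#' @export
similarity_verdict <- function(comparisons, min_similar_features = 11L) {
  stopifnot(inherits(comparisons, "feature_comparison"))
  n_sim <- sum(comparisons$similar)
  list(similar = n_sim >= min_similar_features,
       n_similar = n_sim,
       n_similar_shape = sum(comparisons$similar &
                               comparisons$feature_type == "shape"),
       n_similar_density = sum(comparisons$similar &
                                 comparisons$feature_type == "density"),
       n_tested = nrow(comparisons),
       min_similar_features = min_similar_features)
}

#' Equivalence test (two one-sided tests) for one feature
#'
#' Statistically positive alternative to reading similarity from
#' non-rejection: declares the group means equivalent when the
#' (1 - 2 alpha) confidence interval of the difference lies within
#' +/- margin.
#'
#' @param xs,ys numeric samples.
#' @param margin equivalence margin on the difference of means.
#' @param alpha test level.
#' @return list with `equivalent`, `p_value` (larger of the two
#'   one-sided p-values), `ci`.
#' @export
tost_equivalence <- function(xs, ys, margin, alpha = 0.05) {
  stopifnot(margin > 0)
  d <- mean(xs) - mean(ys)
  se <- sqrt(stats::var(xs) / length(xs) + stats::var(ys) / length(ys))
  df <- se^4 / (stats::var(xs)^2 / (length(xs)^2 * (length(xs) - 1)) +
                  stats::var(ys)^2 / (length(ys)^2 * (length(ys) - 1)))
  t_lo <- (d + margin) / se   # H0: d <= -margin
  t_hi <- (d - margin) / se   # H0: d >= margin
  p <- max(stats::pt(t_lo, df, lower.tail = FALSE), stats::pt(t_hi, df))
  ci <- d + c(-1, 1) * stats::qt(1 - alpha, df) * se
  list(equivalent = p < alpha, p_value = p, ci = ci, df = df)
}

#' Density plot of one feature across region kinds
#'
#' Overlays the total/overlap/specific distributions of one feature for
#' the two models of a comparison.
#' @param feature_rows data.frame from [region_feature_pipeline()] pooled
#'   over patches.
#' @param feature feature column to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot_feature_distributions <- function(feature_rows, feature, ...) {
  kinds <- unique(feature_rows$region_kind)
  vals <- lapply(kinds, function(k) {
    v <- feature_rows[[feature]][feature_rows$region_kind == k]
    v[is.finite(v)]
  })
  ok <- vapply(vals, function(v) length(v) >= 2L, logical(1))
  kinds <- kinds[ok]; vals <- vals[ok]
  if (!length(kinds)) { message("nothing to plot for ", feature); return(invisible(NULL)) }
  dens <- lapply(vals, stats::density)
  xr <- range(unlist(lapply(dens, `[[`, "x")))
  yr <- range(unlist(lapply(dens, `[[`, "y")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = feature, ylab = "density",
                 main = nucleus_feature_names()[[feature]], ...)
  for (i in seq_along(dens)) graphics::lines(dens[[i]], col = i, lwd = 2)
  graphics::legend("topright", kinds, col = seq_along(kinds), lwd = 2,
                   bty = "n")
  invisible(NULL)
}

#' Write a feature comparison table as TSV
#'
#' Table layout mirrors the reporting convention: feature type, display
#' name, one p-value column per group pair.
#' @param comparisons a `feature_comparison` or named list of them
#'   (names = pair labels).
#' @param path output file.
#' @export
write_feature_comparisons <- function(comparisons, path) {
  if (inherits(comparisons, "feature_comparison"))
    comparisons <- list(pair = comparisons)
  base <- comparisons[[1]][, c("feature_type", "display_name")]
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    base[[paste0("p_value_", nm)]] <-
      cmp$p_value[match(base$display_name, cmp$display_name)]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(base, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
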