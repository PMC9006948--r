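# End-to-end study driver: synthetic data -> per-organ training ->
# cross-inference matrix -> attention overlap -> nucleus features ->
# feature statistics, with stage-level caching, a run manifest, and
# byte-stable serialized outputs.

#' Study configuration
#'
#' Validates the declarative configuration that drives [run_study()].
#' Can also be loaded from a YAML file via [read_study_config()].
#'
#' @param n_organs number of synthetic organs.
#' @param shared_pairs list of length-2 character vectors naming organs
#'   with shared cancer morphology.
#' @param comparison_pairs ordered model/organ pairs for the attention
#'   and nucleus stages as a list of c(model_organ, patch_organ); NULL =
#'   all ordered pairs of distinct organs.
#' @param n_patches_per_class,patch_size forwarded to the generator.
#' @param seed master seed for the whole study.
#' @param backbone,epochs,batch_size,learning_rate,optimizer training
#'   settings (used when `search = FALSE`).
#' @param augment_crop enable random-crop augmentation during training
#'   (flips are always on).  Off by default at desk scale: resizing a
#'   90% crop back up blurs the few-pixel nucleus textures the task
#'   rests on; enable it for larger patches.
#' @param search run the hyperparameter search per organ.
#' @param search_trials,search_epochs,final_epochs search settings.
#' @param similarity_threshold accuracy threshold for [flag_similar()].
#' @param cancer_prob_min own-model probability gate for the attention
#'   stage.
#' @param attention_splits dataset splits whose cancer patches feed the
#'   attention/morphometry stages.  Default val + test: the morphometry
#'   comparison needs more samples than the small held-out split alone,
#'   but a model's attention on its own memorized training patches is
#'   not representative, so train patches are excluded.
#' @param n_attention_patches cap on qualifying patches per comparison
#'   pair (first qualifying in dataset order).
#' @param attention_mode mask convention for model-pair comparison:
#'   `"quantile"` (default; equal-coverage masks) or `"value"`, see
#'   [threshold_high_attention()].
#' @param attention_threshold CAM cutoff for value-mode masks.
#' @param attention_quantile coverage cutoff for quantile-mode masks.
#' @param alpha t-test similarity level.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_organs = 3L,
                         shared_pairs = list(c("A", "B")),
                         comparison_pairs = NULL,
                         n_patches_per_class = 100L,
                         patch_size = 64L,
                         seed = 1L,
                         backbone = "small_cnn",
                         epochs = 40L,
                         batch_size = 32L,
                         learning_rate = 3e-3,
                         optimizer = "adam",
                         augment_crop = FALSE,
                         search = FALSE,
                         search_trials = 20L,
                         search_epochs = 20L,
                         final_epochs = 50L,
                         similarity_threshold = 0.9,
                         cancer_prob_min = 0.98,
                         attention_splits = c("val", "test"),
                         n_attention_patches = 24L,
                         attention_mode = c("quantile", "value"),
                         attention_threshold = 0.6,
                         attention_quantile = 0.7,
                         alpha = 0.05) {
  attention_mode <- match.arg(attention_mode)
  organs <- LETTERS[seq_len(n_organs)]
  for (p in shared_pairs) {
    bad <- setdiff(p, organs)
    if (length(bad))
      stop("config field `shared_pairs`: unknown organ id \"", bad[1], "\"")
  }
  if (is.null(comparison_pairs)) {
    comparison_pairs <- list()
    for (a in organs) for (b in organs)
      if (a != b) comparison_pairs[[length(comparison_pairs) + 1L]] <- c(a, b)
  }
  for (p in comparison_pairs) {
    bad <- setdiff(p, organs)
    if (length(bad))
      stop("config field `comparison_pairs`: unknown organ id \"", bad[1], "\"")
  }
  stopifnot(n_patches_per_class >= 10, patch_size >= 64, epochs >= 0,
            similarity_threshold >= 0, similarity_threshold <= 1,
            cancer_prob_min >= 0, cancer_prob_min <= 1,
            attention_threshold >= 0, attention_threshold <= 1,
            alpha > 0, alpha <= 1)
  structure(list(n_organs = as.integer(n_organs), organs = organs,
                 shared_pairs = shared_pairs,
                 comparison_pairs = comparison_pairs,
                 n_patches_per_class = as.integer(n_patches_per_class),
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed),
                 backbone = backbone, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 augment_crop = isTRUE(augment_crop),
                 search = isTRUE(search),
                 search_trials = as.integer(search_trials),
                 search_epochs = as.integer(search_epochs),
                 final_epochs = as.integer(final_epochs),
                 similarity_threshold = similarity_threshold,
                 cancer_prob_min = cancer_prob_min,
                 attention_splits = attention_splits,
                 n_attention_patches = as.integer(n_attention_patches),
                 attention_mode = attention_mode,
                 attention_threshold = attention_threshold,
                 attention_quantile = attention_quantile,
                 alpha = alpha),
            class = "study_config")
}

#' Read a study configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [study_config()].
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$shared_pairs))
    raw$shared_pairs <- lapply(raw$shared_pairs, unlist)
  if (!is.null(raw$comparison_pairs))
    raw$comparison_pairs <- lapply(raw$comparison_pairs, unlist)
  do.call(study_config, raw)
}

#' Run the full cross-organ study
#'
#' Executes synthetic generation, per-organ training (optionally with
#' hyperparameter search), cross-organ inference, attention overlap for
#' the configured pairs, nucleus morphometry, and feature statistics.
#' Every stage writes its outputs under `out_dir` and is resumed from
#' cache on rerun (delete a stage file to recompute just that stage).
#'
#' @param config a `study_config` (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @param force recompute all stages, ignoring caches.
#' @param verbose print stage progress.
#' @return an object of class `crossorgan_study` with the matrix,
#'   similarity flags, overlap reports, feature tables, comparisons,
#'   verdicts, and the run manifest.
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("study_"),
                      force = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(config = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list(), warnings = character(0))
  note <- function(stage, status, files = character(0)) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      status = status,
      files = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))),
      at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  }
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # --- stage 1: synthetic datasets ----------------------------------------
  data_file <- file.path(out_dir, "datasets.rds")
  if (!force && file.exists(data_file)) {
    say("* datasets: cached")
    datasets <- readRDS(data_file)
    note("datasets", "cached", data_file)
  } else {
    say("* datasets: generating ", config$n_organs, " organs")
    specs <- generate_shared_morphology_study(
      config$n_organs, config$shared_pairs, base_seed = config$seed,
      n_patches_per_class = config$n_patches_per_class,
      patch_size = config$patch_size)
    datasets <- lapply(specs, generate_organ_dataset)
    saveRDS(datasets, data_file)
    note("datasets", "computed", data_file)
  }

  # --- stage 2: per-organ models ------------------------------------------
  model_file <- file.path(out_dir, "models.rds")
  if (!force && file.exists(model_file)) {
    say("* models: cached")
    models <- readRDS(model_file)
    note("models", "cached", model_file)
  } else {
    models <- list()
    for (organ in config$organs) {
      say("* training model for organ ", organ)
      spec <- model_spec(backbone = config$backbone,
                         input_size = config$patch_size)
      if (config$search) {
        sr <- hyperparameter_search(
          datasets[[organ]],
          search_space(n_trials = config$search_trials,
                       epochs_per_trial = config$search_epochs,
                       final_epochs = config$final_epochs),
          base_spec = spec,
          seed = derive_seed(config$seed, paste0("search_", organ)),
          batch_size = config$batch_size)
        spec <- sr$best_spec
        tcfg <- sr$best_config
      } else {
        # one shared initialization across organs (the role a common
        # pretrained backbone plays): attention maps stay comparable
        tcfg <- train_config(optimizer = config$optimizer,
                             learning_rate = config$learning_rate,
                             batch_size = config$batch_size,
                             epochs = config$epochs,
                             augment_crop = config$augment_crop,
                             seed = derive_seed(config$seed,
                                                paste0("train_", organ)),
                             init_seed = derive_seed(config$seed,
                                                     "shared_init"))
      }
      models[[organ]] <- fit_patch_classifier(datasets[[organ]], spec, tcfg)
    }
    saveRDS(models, model_file)
    note("models", "computed", model_file)
  }

  # --- stage 3: cross-organ inference -------------------------------------
  matrix_file <- file.path(out_dir, "cross_matrix.tsv")
  say("* cross-organ inference")
  cm <- wcollect(cross_matrix(models, datasets))
  write_cross_matrix(cm, matrix_file)
  jsonlite::write_json(
    list(organs = cm$organs, accuracy = cm$accuracy, auc = cm$auc, f1 = cm$f1),
    file.path(out_dir, "cross_matrix.json"), digits = NA)
  similar <- flag_similar(cm, config$similarity_threshold)
  note("crossinfer", "computed",
       c(matrix_file, file.path(out_dir, "cross_matrix.json")))

  # --- stage 4 + 5: attention overlap and nucleus features ----------------
  overlap_file <- file.path(out_dir, "overlap.tsv")
  features_file <- file.path(out_dir, "nucleus_features.tsv")
  if (!force && file.exists(overlap_file) && file.exists(features_file)) {
    say("* attention/nucleus: cached")
    overlap_scores <- utils::read.delim(overlap_file)
    feature_rows <- utils::read.delim(features_file)
    note("attention", "cached", overlap_file)
    note("nucleus", "cached", features_file)
  } else {
    overlap_scores <- NULL; feature_rows <- NULL
    for (p in config$comparison_pairs) {
      say("* attention overlap: model ", p[1], " vs ", p[2],
          " on ", p[2], " patches")
      ds <- datasets[[p[2]]]
      idx <- which(ds$meta$class == "cancer" &
                     ds$meta$split %in% config$attention_splits)
      idx <- idx[order(ds$meta$id[idx])]
      patches <- ds$records[idx]
      ids <- ds$meta$id[idx]
      prob <- predict(models[[p[2]]], patches, type = "prob")[, "cancer"]
      qual <- which(prob > config$cancer_prob_min)
      if (length(qual) > config$n_attention_patches)
        qual <- qual[seq_len(config$n_attention_patches)]
      if (!length(qual)) {
        manifest$warnings <- c(manifest$warnings, paste0(
          "no qualifying patches for pair ", p[1], "-", p[2]))
        next
      }
      for (q in qual) {
        cam_a <- gradcam(models[[p[1]]], patches[[q]], "cancer")
        cam_b <- gradcam(models[[p[2]]], patches[[q]], "cancer")
        ma <- threshold_high_attention(cam_a, config$attention_mode,
                                       threshold = config$attention_threshold,
                                       quantile = config$attention_quantile)
        mb <- threshold_high_attention(cam_b, config$attention_mode,
                                       threshold = config$attention_threshold,
                                       quantile = config$attention_quantile)
        overlap_scores <- rbind(overlap_scores, data.frame(
          model_organ = p[1], patch_organ = p[2], patch_id = ids[q],
          iou_boxes = suppressWarnings(
            iou_boxes(boxes_from_mask(ma), boxes_from_mask(mb))),
          jaccard_pixels = suppressWarnings(jaccard_masks(ma, mb))))
        fr <- wcollect(region_feature_pipeline(
          patches[[q]], ma, mb, patch_id = ids[q]))
        fr$model_organ <- p[1]; fr$patch_organ <- p[2]
        feature_rows <- rbind(feature_rows, fr)
      }
    }
    if (is.null(overlap_scores))
      overlap_scores <- data.frame(model_organ = character(0),
                                   patch_organ = character(0),
                                   patch_id = character(0),
                                   iou_boxes = numeric(0),
                                   jaccard_pixels = numeric(0))
    for (df_ in list(list(overlap_scores, overlap_file),
                     list(feature_rows, features_file))) {
      con <- file(df_[[2]], "wb")
      utils::write.table(df_[[1]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    note("attention", "computed", overlap_file)
    note("nucleus", "computed", features_file)
  }

  # --- stage 6: feature statistics ----------------------------------------
  stats_file <- file.path(out_dir, "feature_comparisons.tsv")
  say("* feature statistics")
  comparisons <- list(); verdicts <- list()
  if (!is.null(feature_rows) && nrow(feature_rows)) {
    for (p in config$comparison_pairs) {
      key <- paste0(p[1], "_", p[2])
      sel <- feature_rows$model_organ == p[1] & feature_rows$patch_organ == p[2]
      ta <- feature_rows[sel & feature_rows$region_kind == "a_total", ]
      tb <- feature_rows[sel & feature_rows$region_kind == "b_total", ]
      if (nrow(ta) < 2L || nrow(tb) < 2L) next
      cmp <- suppressMessages(
        compare_feature_tables(ta, tb, alpha = config$alpha))
      if (is.null(cmp) || !nrow(cmp)) next
      comparisons[[key]] <- cmp
      verdicts[[key]] <- similarity_verdict(cmp)
    }
    if (length(comparisons))
      write_feature_comparisons(comparisons, stats_file)
  }
  note("stats", "computed", stats_file)

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(config = config, out_dir = out_dir,
                 datasets = datasets, models = models,
                 matrix = cm, similar = similar,
                 overlap = overlap_scores, features = feature_rows,
                 comparisons = comparisons, verdicts = verdicts,
                 manifest = manifest),
            class = "crossorgan_study")
}

#' @export
print.crossorgan_study <- function(x, ...) {
  cat("Cross-organ study:", length(x$config$organs), "organs (",
      paste(x$config$organs, collapse = ", "), ")\n")
  print(x$matrix)
  sim <- x$similar[x$similar$similar, , drop = FALSE]
  if (nrow(sim)) {
    cat("Similar pairs (accuracy > ", x$config$similarity_threshold, "):\n",
        sep = "")
    for (i in seq_len(nrow(sim)))
      cat(sprintf("  %s -> %s (%.3f)\n", sim$model_organ[i],
                  sim$test_organ[i], sim$accuracy[i]))
  } else cat("No similar pairs flagged.\n")
  invisible(x)
}

#' @export
summary.crossorgan_study <- function(object, ...) {
  print(object)
  if (length(object$verdicts)) {
    cat("\nMorphometry verdicts (similar features / tested):\n")
    for (nm in names(object$verdicts)) {
      v <- object$verdicts[[nm]]
      cat(sprintf("  %s: %d/%d (shape %d, density %d) -> %s\n", nm,
                  v$n_similar, v$n_tested, v$n_similar_shape,
                  v$n_similar_density,
                  if (v$similar) "similar" else "not similar"))
    }
  }
  if (!is.null(object$overlap) && nrow(object$overlap)) {
    cat("\nMean attention overlap by pair:\n")
    agg <- stats::aggregate(
      cbind(iou_boxes, jaccard_pixels) ~ model_organ + patch_organ,
      data = object$overlap, FUN = mean)
    print(agg, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.crossorgan_study <- function(x, ...) plot(x$matrix, ...)
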