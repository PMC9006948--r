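# Hyperparameter search over optimizer, learning rate, dropout, and the
# fully connected head geometry, maximizing validation accuracy.  The
# default sampler is a lightweight tree-of-Parzen-estimators scheme
# (random startup trials, then candidates scored by a good/bad kernel
# density ratio); a pure random sampler is available.

#' Hyperparameter search space
#'
#' Bounds follow the usual practice for this task family: categorical
#' optimizer in {adam, rmsprop, sgd}, learning rate log-uniform on
#' [1e-5, 1e-1], dropout uniform on [0.2, 0.5], 1-3 FCN layers with
#' 4-128 neurons per layer; 20 trials of 20 epochs each, then a 50-epoch
#' final fit.
#'
#' @param n_trials number of search trials.
#' @param epochs_per_trial training epochs per trial.
#' @param final_epochs epochs of the final fit with the best config.
#' @param lr_range,dropout_range,layer_range,neuron_range bounds.
#' @param optimizers categorical choices.
#' @return an object of class `search_space`.
#' @export
search_space <- function(n_trials = 20L, epochs_per_trial = 20L,
                         final_epochs = 50L,
                         lr_range = c(1e-5, 1e-1),
                         dropout_range = c(0.2, 0.5),
                         layer_range = c(1L, 3L),
                         neuron_range = c(4L, 128L),
                         optimizers = c("adam", "rmsprop", "sgd")) {
  stopifnot(n_trials >= 1, epochs_per_trial >= 1, final_epochs >= 0,
            lr_range[1] > 0, lr_range[1] < lr_range[2],
            dropout_range[1] >= 0, dropout_range[2] <= 1,
            layer_range[1] >= 1, layer_range[2] <= 3,
            neuron_range[1] >= 4, neuron_range[2] <= 128)
  structure(list(n_trials = as.integer(n_trials),
                 epochs_per_trial = as.integer(epochs_per_trial),
                 final_epochs = as.integer(final_epochs),
                 lr_range = lr_range, dropout_range = dropout_range,
                 layer_range = as.integer(layer_range),
                 neuron_range = as.integer(neuron_range),
                 optimizers = optimizers),
            class = "search_space")
}

#' Draw one configuration from a search space
#'
#' Learning rate is log-uniform; dropout uniform; layer count and
#' neurons-per-layer integer-uniform; one dropout and one width drawn per
#' layer.  Consumes the current RNG stream.
#' @param space a `search_space`.
#' @return list with `optimizer`, `learning_rate`, `fcn_layers`,
#'   `fcn_widths`, `fcn_dropouts`.
#' @export
sample_search_space <- function(space) {
  nl <- sample(space$layer_range[1]:space$layer_range[2], 1L)
  list(optimizer = sample(space$optimizers, 1L),
       learning_rate = exp(stats::runif(1, log(space$lr_range[1]),
                                        log(space$lr_range[2]))),
       fcn_layers = nl,
       fcn_widths = sample(space$neuron_range[1]:space$neuron_range[2], nl,
                           replace = TRUE),
       fcn_dropouts = stats::runif(nl, space$dropout_range[1],
                                   space$dropout_range[2]))
}

# Score candidates by a per-dimension Parzen density ratio good/bad.
.tpe_propose <- function(space, trials, n_candidates = 24L) {
  ok <- !vapply(trials, function(t) is.null(t$val_acc) || is.na(t$val_acc),
                logical(1))
  hist <- trials[ok]
  accs <- vapply(hist, `[[`, numeric(1), "val_acc")
  n_good <- max(1L, ceiling(length(hist) * 0.3))
  good <- hist[order(-accs)][seq_len(n_good)]
  bad <- hist[order(-accs)][-seq_len(n_good)]
  dens <- function(x, obs, bw) {
    if (!length(obs)) return(1)
    mean(stats::dnorm(x, obs, bw)) + 1e-12
  }
  cat_score <- function(value, set) {
    if (!length(set)) return(1)
    (sum(vapply(set, function(t) t$config$optimizer == value, logical(1))) + 1) /
      (length(set) + 3)
  }
  cands <- replicate(n_candidates, sample_search_space(space), simplify = FALSE)
  scores <- vapply(cands, function(cf) {
    lg <- log10(cf$learning_rate)
    lg_good <- log10(vapply(good, function(t) t$config$learning_rate, numeric(1)))
    lg_bad <- log10(vapply(bad, function(t) t$config$learning_rate, numeric(1)))
    dr <- mean(cf$fcn_dropouts)
    dr_good <- vapply(good, function(t) mean(t$config$fcn_dropouts), numeric(1))
    dr_bad <- vapply(bad, function(t) mean(t$config$fcn_dropouts), numeric(1))
    log(dens(lg, lg_good, 0.5)) - log(dens(lg, lg_bad, 0.5)) +
      log(dens(dr, dr_good, 0.1)) - log(dens(dr, dr_bad, 0.1)) +
      log(cat_score(cf$optimizer, good)) - log(cat_score(cf$optimizer, bad))
  }, numeric(1))
  cands[[which.max(scores)]]
}

#' Hyperparameter search for a patch classifier
#'
#' Runs `space$n_trials` trials of `space$epochs_per_trial` epochs each
#' and returns the configuration with the maximum validation accuracy
#' (ties broken by earliest trial).  Failed trials are recorded with NA
#' accuracy and skipped, not fatal.
#'
#' @param dataset a `patch_dataset`.
#' @param space a `search_space`.
#' @param base_spec a `model_spec` whose backbone/input settings are kept
#'   while the head geometry is searched.
#' @param sampler `"tpe"` (default; 10 random startup trials, then
#'   Parzen-ratio proposals) or `"random"`.
#' @param seed master seed.
#' @param batch_size training batch size for the trials.
#' @return list with `best_config` (a `train_config`), `best_spec` (a
#'   `model_spec`), `best_trial`, and `trials` (data.frame log).
#' @export
hyperparameter_search <- function(dataset, space = search_space(),
                                  base_spec = model_spec(),
                                  sampler = c("tpe", "random"),
                                  seed = 1L, batch_size = 32L) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(dataset, "patch_dataset"), inherits(space, "search_space"))
  trials <- list()
  n_startup <- 10L
  for (tr in seq_len(space$n_trials)) {
    cf <- with_seed(derive_seed(seed, paste0("trial", tr)), {
      if (sampler == "tpe" && tr > n_startup && length(trials) >= 2L)
        .tpe_propose(space, trials)
      else sample_search_space(space)
    })
    spec <- model_spec(backbone = base_spec$backbone,
                       fcn_layers = cf$fcn_layers,
                       fcn_widths = cf$fcn_widths,
                       fcn_dropouts = cf$fcn_dropouts,
                       input_size = base_spec$input_size,
                       channels = base_spec$channels)
    tcfg <- train_config(optimizer = cf$optimizer,
                         learning_rate = cf$learning_rate,
                         batch_size = batch_size,
                         epochs = space$epochs_per_trial,
                         seed = derive_seed(seed, "trial_fit"))
    fit <- tryCatch(fit_patch_classifier(dataset, spec, tcfg),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      trials[[tr]] <- list(trial = tr, config = cf, val_acc = NA_real_,
                           error = conditionMessage(fit))
    } else {
      trials[[tr]] <- list(trial = tr, config = cf, val_acc = fit$best_val_acc,
                           error = NA_character_)
    }
  }
  accs <- vapply(trials, `[[`, numeric(1), "val_acc")
  if (all(is.na(accs))) stop("every search trial failed")
  best_i <- which(accs == max(accs, na.rm = TRUE))[1]  # earliest-trial tie-break
  bc <- trials[[best_i]]$config
  log_df <- data.frame(
    trial = seq_along(trials),
    optimizer = vapply(trials, function(t) t$config$optimizer, ""),
    learning_rate = vapply(trials, function(t) t$config$learning_rate, 0),
    fcn_layers = vapply(trials, function(t) t$config$fcn_layers, 0L),
    fcn_widths = vapply(trials, function(t)
      paste(t$config$fcn_widths, collapse = ","), ""),
    mean_dropout = vapply(trials, function(t) mean(t$config$fcn_dropouts), 0),
    val_acc = accs,
    error = vapply(trials, function(t)
      if (is.null(t$error)) NA_character_ else t$error, ""))
  list(best_config = train_config(optimizer = bc$optimizer,
                                  learning_rate = bc$learning_rate,
                                  batch_size = batch_size,
                                  epochs = space$final_epochs,
                                  seed = derive_seed(seed, "final_fit")),
       best_spec = model_spec(backbone = base_spec$backbone,
                              fcn_layers = bc$fcn_layers,
                              fcn_widths = bc$fcn_widths,
                              fcn_dropouts = bc$fcn_dropouts,
                              input_size = base_spec$input_size,
                              channels = base_spec$channels),
       best_trial = best_i,
       trials = log_df)
}
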