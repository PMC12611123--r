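# End-to-end assembly: leakage-guarded preparation, variant training,
# prediction and benchmark evaluation.

#' Prepare a panel for training without temporal leakage
#'
#' Cleans the panel, slices windows, fixes the chronological split, then
#' computes every data-dependent statistic — the calendar-month
#' climatology used for seasonal adjustment of temperature and
#' precipitation, and the per-variable standardization statistics — from
#' the training block only, and applies them panel-wide.
#'
#' @param panel A `vegr_panel` (raw; may contain missing cells).
#' @param cfg A [train_config()].
#' @param task Target task, as in [make_windows()].
#' @param max_windows Optional cap: keep only the chronologically first
#'   `max_windows` windows (the benchmark uses 3217).
#' @return A `vegr_prep` list: `windows` (standardized, seasonally
#'   adjusted), `y` (raw-scale targets), `split`, `standardizer`,
#'   `climatology`, `cfg`, `task`.
#' @export
prepare_splits <- function(panel, cfg = train_config(),
                           task = "restoration_rate",
                           max_windows = NULL) {
  panel <- preprocess_panel(panel)
  ds_raw <- make_windows(panel, T_steps = cfg$T_steps, task = task)
  if (!is.null(max_windows) && n_windows(ds_raw) > max_windows)
    ds_raw <- ds_subset(ds_raw, seq_len(max_windows))
  split <- chrono_split(ds_raw, cfg$split)
  train_end <- max(ds_raw$window_end[split$train])
  clim <- climatology(panel, max_month_index = train_end)
  panel_adj <- structure(lapply(panel, seasonal_adjust, clim = clim),
                         class = "vegr_panel", config = attr(panel, "config"))
  ds <- make_windows(panel_adj, T_steps = cfg$T_steps, task = task)
  if (!is.null(max_windows) && n_windows(ds) > max_windows)
    ds <- ds_subset(ds, seq_len(max_windows))
  stdzr <- fit_standardizer(ds, split$train)
  ds <- apply_standardizer(ds, stdzr)
  structure(list(windows = ds, split = split, standardizer = stdzr,
                 climatology = clim, cfg = cfg, task = task),
            class = "vegr_prep")
}

#' Train one model variant
#'
#' Variants:
#' \describe{
#'   \item{`full`}{Cubist rule features -> 2-layer BiGRU -> self-attention
#'     -> affine head (the hybrid architecture).}
#'   \item{`cubist_only`}{the Cubist layer's prediction at the window's
#'     final step; no neural network.}
#'   \item{`bigru_only`}{raw standardized covariates -> 2-layer BiGRU ->
#'     mean pooling -> head (no Cubist, no attention).}
#'   \item{`cubist_gru`}{Cubist features -> 2-layer unidirectional GRU ->
#'     final state -> head (no attention, no backward pass).}
#' }
#' The Cubist layer and all statistics derive from the training block
#' only; the network minimizes mean-squared error on standardized targets
#' with Adam, early-stopping on validation loss.
#'
#' @param prep A `vegr_prep` from [prepare_splits()].
#' @param variant One of `"full"`, `"cubist_only"`, `"bigru_only"`,
#'   `"cubist_gru"`.
#' @param verbose Print per-epoch losses.
#' @return A `vegr_model` with the fitted components and `history`
#'   (per-epoch train/validation loss, `best_epoch`, `stopped_epoch`).
#' @export
train_model <- function(prep,
                        variant = c("full", "cubist_only", "bigru_only",
                                    "cubist_gru"),
                        verbose = FALSE) {
  variant <- match.arg(variant)
  cfg <- prep$cfg
  ds <- prep$windows
  split <- prep$split
  stdzr <- prep$standardizer
  y_std <- standardize_y(ds$y, stdzr)

  cubist <- NULL
  if (variant != "bigru_only") {
    cubist <- fit_cubist_layer(ds$X[split$train, , , drop = FALSE],
                               y_std[split$train],
                               min_leaf = cfg$min_leaf,
                               max_rules = cfg$max_rules)
  }
  if (variant == "cubist_only") {
    model <- structure(list(variant = variant, cubist = cubist, nn = NULL,
                            prep_meta = prep_meta(prep),
                            history = NULL),
                       class = "vegr_model")
    return(model)
  }
  feats <- feature_array(variant, cubist, ds$X, cfg)
  net_cfg <- switch(variant,
    full = model_config(cfg$m, hidden = cfg$hidden, n_layers = cfg$n_layers,
                        bidirectional = TRUE, aggregator = "attention",
                        d_k = cfg$d_k, dropout = cfg$dropout),
    bigru_only = model_config(cfg$D, hidden = cfg$hidden,
                              n_layers = cfg$n_layers, bidirectional = TRUE,
                              aggregator = "mean", dropout = cfg$dropout),
    cubist_gru = model_config(cfg$m, hidden = cfg$hidden,
                              n_layers = cfg$n_layers, bidirectional = FALSE,
                              aggregator = "last", dropout = cfg$dropout))
  fit <- nn_train(feats[split$train, , , drop = FALSE], y_std[split$train],
                  feats[split$val, , , drop = FALSE], y_std[split$val],
                  net_cfg,
                  lr = cfg$learning_rate, batch_size = cfg$batch_size,
                  max_epochs = cfg$max_epochs, patience = cfg$patience,
                  seed = cfg$seed, verbose = verbose)
  structure(list(variant = variant, cubist = cubist,
                 nn = list(params = fit$params, cfg = net_cfg),
                 prep_meta = prep_meta(prep),
                 history = fit[c("history", "best_epoch", "stopped_epoch")]),
            class = "vegr_model")
}

prep_meta <- function(prep) {
  list(standardizer = prep$standardizer, climatology = prep$climatology,
       cfg = prep$cfg, task = prep$task)
}

# Per-variant input feature array from standardized covariates.
feature_array <- function(variant, cubist, X, cfg) {
  if (variant == "bigru_only") return(X)
  cubist_featurize_windows(cubist, X, m = cfg$m)
}

#' Predict from a trained variant
#'
#' @param object A `vegr_model`.
#' @param ds A standardized `window_dataset` (as in `prep$windows`).
#' @param idx Optional window indices to predict (default: all).
#' @param ... Unused.
#' @return List with `pred` (original target scale) and, for the full
#'   variant, `alpha` (per-window attention importance over time steps).
#' @export
predict.vegr_model <- function(object, ds, idx = NULL, ...) {
  if (is.null(idx)) idx <- seq_len(n_windows(ds))
  stdzr <- object$prep_meta$standardizer
  cfg <- object$prep_meta$cfg
  X <- ds$X[idx, , , drop = FALSE]
  if (object$variant == "cubist_only") {
    # Cubist prediction at the window's final step
    last_step <- matrix(X[, dim(X)[2], ], nrow = dim(X)[1])
    z <- predict(object$cubist, last_step)
    return(list(pred = unstandardize_y(z, stdzr), alpha = NULL))
  }
  feats <- feature_array(object$variant, object$cubist, X, cfg)
  out <- nn_predict(object$nn$params, object$nn$cfg, feats)
  list(pred = unstandardize_y(out$yhat, stdzr), alpha = out$alpha)
}

#' Evaluate a trained variant on one split
#'
#' @param model A `vegr_model`.
#' @param prep The `vegr_prep` it was trained from.
#' @param which_split `"train"`, `"val"` or `"test"`.
#' @return List with `metrics` ([evaluate()]), `by_band`
#'   ([accuracy_by_group()]), `pred`, `truth`, `errors`.
#' @export
evaluate_split <- function(model, prep, which_split = "test") {
  idx <- prep$split[[which_split]]
  pr <- predict(model, prep$windows, idx)
  truth <- prep$windows$y[idx]
  list(metrics = evaluate(pr$pred, truth),
       by_band = accuracy_by_group(pr$pred, truth,
                                   prep$windows$altitude_band[idx]),
       pred = pr$pred, truth = truth, errors = pr$pred - truth,
       alpha = pr$alpha)
}

#' Run the synthetic benchmark end to end
#'
#' Generates (or accepts) a panel, prepares leakage-free splits, trains
#' the requested variants and evaluates each on validation and test
#' blocks.
#'
#' @param config Scenario configuration for panel generation (ignored if
#'   `panel` is given).
#' @param cfg A [train_config()].
#' @param variants Character vector of variants to train.
#' @param panel Optional pre-generated panel.
#' @param task Target task.
#' @param max_windows Window cap (default 3217 under benchmark sizing).
#' @param verbose Print progress.
#' @return List with `prep`, `models`, `results` (per-variant evaluation
#'   lists with `val` and `test` entries) and `comparisons` (paired
#'   t-tests of each ablation against the full model, when trained).
#' @export
run_benchmark <- function(config = scenario_config(),
                          cfg = train_config(),
                          variants = c("full", "cubist_only", "bigru_only",
                                       "cubist_gru"),
                          panel = NULL, task = "restoration_rate",
                          max_windows = 3217L, verbose = FALSE) {
  if (is.null(panel)) panel <- generate_panel(config)
  prep <- prepare_splits(panel, cfg, task = task, max_windows = max_windows)
  models <- list()
  results <- list()
  for (v in variants) {
    if (verbose) message("training variant: ", v)
    models[[v]] <- train_model(prep, v, verbose = verbose)
    results[[v]] <- list(val = evaluate_split(models[[v]], prep, "val"),
                         test = evaluate_split(models[[v]], prep, "test"))
  }
  comparisons <- NULL
  if ("full" %in% variants && length(variants) > 1) {
    comparisons <- lapply(setdiff(variants, "full"), function(v)
      c(list(variant = v),
        compare_models(results[[v]]$test$errors, results$full$test$errors)))
    names(comparisons) <- setdiff(variants, "full")
  }
  list(prep = prep, models = models, results = results,
       comparisons = comparisons)
}

#' Tidy metrics table for a benchmark run
#'
#' @param results The `results` element of [run_benchmark()].
#' @return Data frame with one row per (variant, split, band) including
#'   the pooled rows (`band = "all"`).
#' @export
metrics_table <- function(results) {
  rows <- list()
  for (v in names(results)) for (s in names(results[[v]])) {
    ev <- results[[v]][[s]]
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, split = s, band = "all",
      rmse = ev$metrics$rmse, mape = ev$metrics$mape, r2 = ev$metrics$r2,
      accuracy = ev$metrics$accuracy, n = ev$metrics$n)
    for (b in names(ev$by_band)) {
      m <- ev$by_band[[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, split = s, band = b, rmse = m$rmse, mape = m$mape,
        r2 = m$r2, accuracy = m$accuracy, n = m$n)
    }
  }
  do.call(rbind, rows)
}
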