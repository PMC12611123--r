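#' Training configuration
#'
#' Defaults follow the benchmark protocol: 30-month windows of 6
#' covariates, 16 Cubist features, two 64-unit BiGRU layers with 0.3
#' inter-layer dropout, Adam at learning rate 0.001, batch size 32, at
#' most 100 epochs with early stopping patience 10, and a chronological
#' 70/20/10 train/validation/test split.
#'
#' @param T_steps,D,m,hidden,n_layers,dropout,learning_rate,batch_size
#'   Architecture and optimization settings (see Details in the package
#'   vignette).
#' @param max_epochs,patience Early-stopping protocol: training stops when
#'   the validation loss fails to improve by more than 1e-6 for `patience`
#'   consecutive epochs; the best-epoch weights are restored.
#' @param split Chronological train/validation/test fractions (sum to 1).
#' @param min_leaf,max_rules Cubist layer settings.
#' @param d_k Attention projection width.
#' @param seed Master seed for initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(T_steps = 30L, D = 6L, m = 16L, hidden = 64L,
                         n_layers = 2L, dropout = 0.3,
                         learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 100L, patience = 10L,
                         split = c(0.70, 0.20, 0.10),
                         min_leaf = 20L, max_rules = 14L, d_k = 64L,
                         seed = 42L) {
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  structure(list(T_steps = as.integer(T_steps), D = as.integer(D),
                 m = as.integer(m), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), split = split,
                 min_leaf = as.integer(min_leaf),
                 max_rules = as.integer(max_rules), d_k = as.integer(d_k),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Chronological train / validation / test split
#'
#' Windows are ordered by window end (ties by site id, then window
#' start); the last `round(f_test * N)` form the test set, the previous
#' `round(f_val * N)` the validation set, the remainder the training set,
#' so every test window ends no earlier than every validation window, and
#' every validation window no earlier than every training window.
#'
#' @param ds A `window_dataset`.
#' @param fractions Train/validation/test fractions (default 0.70/0.20/0.10).
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
chrono_split <- function(ds, fractions = c(0.70, 0.20, 0.10)) {
  n <- n_windows(ds)
  if (n < 10) stop("need at least 10 windows to split")
  ord <- order(ds$window_end, ds$site_id, ds$window_start)
  n_test <- round(fractions[3] * n)
  n_val <- round(fractions[2] * n)
  n_train <- n - n_val - n_test
  list(train = ord[seq_len(n_train)],
       val = ord[n_train + seq_len(n_val)],
       test = ord[n_train + n_val + seq_len(n_test)])
}

#' Expanding-window time-series cross-validation folds
#'
#' Fold `i` fits on the first `i` blocks of the chronologically sorted
#' training windows and evaluates on block `i + 1`, with `k + 1` equal
#' blocks in total: evaluation rows are always strictly later than their
#' fit rows, and evaluation blocks are pairwise disjoint.
#'
#' @param n A `window_dataset` (chronologically sorted training windows)
#'   or simply their count.
#' @param k Number of folds (default 5).
#' @return List of `k` lists with integer vectors `fit` and `eval`.
#' @export
ts_cv_folds <- function(n, k = 5L) {
  if (inherits(n, "window_dataset")) n <- n_windows(n)
  if (k < 2) stop("need at least 2 folds")
  block <- floor(n / (k + 1))
  if (block < 1) stop("too few windows for the requested folds")
  lapply(seq_len(k), function(i)
    list(fit = seq_len(i * block),
         eval = (i * block + 1L):((i + 1L) * block)))
}

#' Prediction metric suite
#'
#' RMSE, MAPE (percent), the coefficient of determination and the
#' within-10-percent prediction accuracy: the percentage of samples whose
#' relative error `|yhat - y| / |y|` is at most 0.10 (denominators floored
#' at 1e-8).
#'
#' @param preds,truth Numeric vectors on the original target scale.
#' @return A `vegr_metrics` list: `rmse`, `mape`, `r2`, `accuracy`, `n`.
#' @export
evaluate <- function(preds, truth) {
  if (length(preds) != length(truth) || length(truth) < 1)
    stop("predictions and truth must be equal-length, non-empty")
  err <- preds - truth
  rel <- abs(err) / pmax(abs(truth), 1e-8)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant truth: R^2 undefined")
    NaN
  } else 1 - sum(err^2) / ss_tot
  structure(list(rmse = sqrt(mean(err^2)),
                 mape = 100 * mean(rel),
                 r2 = r2,
                 accuracy = 100 * mean(rel <= 0.10),
                 n = length(truth)),
            class = "vegr_metrics")
}

#' @export
print.vegr_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f | MAPE %.2f%% | R2 %.4f | accuracy(+-10%%) %.1f%% | n = %d\n",
              x$rmse, x$mape, x$r2, x$accuracy, x$n))
  invisible(x)
}

#' Metrics per altitude band
#'
#' @param preds,truth As in [evaluate()].
#' @param groups Factor of altitude-band labels per sample.
#' @return Named list of `vegr_metrics` per band (entries with `n = 0` and
#'   `NA` metrics for empty bands).
#' @export
accuracy_by_group <- function(preds, truth, groups) {
  groups <- as.factor(groups)
  out <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (!length(idx))
      return(structure(list(rmse = NA_real_, mape = NA_real_, r2 = NA_real_,
                            accuracy = NA_real_, n = 0L),
                       class = "vegr_metrics"))
    evaluate(preds[idx], truth[idx])
  })
  names(out) <- levels(groups)
  out
}

#' Paired comparison of two models' prediction errors
#'
#' Paired t-test on per-sample error magnitudes: `d_i = |e_a,i| - |e_b,i|`
#' (signed errors when `absolute = FALSE`), `t = mean(d) / (sd(d) /
#' sqrt(N))` with the sample (N-1) standard deviation and a two-sided p
#' from the t distribution with N-1 degrees of freedom.
#'
#' @param errors_a,errors_b Per-sample prediction errors of the two models
#'   on the same test windows.
#' @param absolute Compare absolute errors (default) or signed errors.
#' @return List `t`, `p`, `mean_diff`, `df`.
#' @export
compare_models <- function(errors_a, errors_b, absolute = TRUE) {
  if (length(errors_a) != length(errors_b)) stop("error vectors differ in length")
  n <- length(errors_a)
  if (n < 3) stop("need at least 3 paired errors")
  d <- if (absolute) abs(errors_a) - abs(errors_b) else errors_a - errors_b
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, mean_diff = 0, df = n - 1L))
    warning("zero variance of error differences: p undefined")
    return(list(t = NaN, p = NaN, mean_diff = mean(d), df = n - 1L))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1),
       mean_diff = mean(d), df = n - 1L)
}
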