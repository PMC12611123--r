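#' Slice a panel into fixed-length model windows
#'
#' Per site, sliding windows of `T` consecutive months (stride 1).  The
#' covariate block of a window is the `T x D` matrix of the six model
#' variables; the target depends on the task:
#' \describe{
#'   \item{`restoration_rate`}{relative FVC change over the window,
#'     `(FVC_end - FVC_start) / max(FVC_start, 0.05)`, computed on
#'     unstandardized FVC.  The floor keeps the relative-error metrics
#'     finite on sparsely vegetated sites.}
#'   \item{`survival`}{vegetation survival rate (percent) at the window's
#'     final month.}
#' }
#'
#' @param panel A preprocessed, gap-free `vegr_panel`.
#' @param T_steps Window length in months (default 30).
#' @param task `"restoration_rate"` (default) or `"survival"`.
#' @return A `window_dataset`: list with `X` (N x T x D array, raw scale),
#'   `y` (length N), `window_start`, `window_end` (0-based month indices),
#'   `site_id`, `altitude_band`, `task`, `vars`.
#' @export
make_windows <- function(panel, T_steps = 30L,
                         task = c("restoration_rate", "survival")) {
  task <- match.arg(task)
  per_site <- list()
  skipped <- 0L
  for (s in panel) {
    m <- nrow(s)
    if (m < T_steps) {
      warning(sprintf("site %s has %d < %d months; skipped",
                      s$site_id[1], m, T_steps))
      skipped <- skipped + 1L
      next
    }
    n_w <- m - T_steps + 1L
    Xs <- array(NA_real_, c(n_w, T_steps, length(PANEL_VARS)))
    mat <- as.matrix(s[, PANEL_VARS])
    for (w in seq_len(n_w)) Xs[w, , ] <- mat[w:(w + T_steps - 1L), ]
    starts <- s$month_index[seq_len(n_w)]
    ends <- starts + T_steps - 1L
    y <- if (task == "restoration_rate") {
      f0 <- s$fvc[seq_len(n_w)]
      f1 <- s$fvc[seq_len(n_w) + T_steps - 1L]
      (f1 - f0) / pmax(f0, 0.05)
    } else {
      s$survival_pct[seq_len(n_w) + T_steps - 1L]
    }
    per_site[[length(per_site) + 1L]] <- list(
      X = Xs, y = y, start = starts, end = ends,
      site = rep(s$site_id[1], n_w),
      band = rep(as.character(altitude_band(s$altitude_m[1])), n_w))
  }
  if (!length(per_site)) stop("all sites shorter than the window length")
  X <- do.call(abind3, lapply(per_site, `[[`, "X"))
  ds <- list(
    X = X,
    y = unlist(lapply(per_site, `[[`, "y")),
    window_start = unlist(lapply(per_site, `[[`, "start")),
    window_end = unlist(lapply(per_site, `[[`, "end")),
    site_id = unlist(lapply(per_site, `[[`, "site")),
    altitude_band = factor(unlist(lapply(per_site, `[[`, "band")),
                           levels = ALTITUDE_BANDS),
    task = task,
    vars = PANEL_VARS
  )
  class(ds) <- "window_dataset"
  chrono_sort(ds)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[-1]
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(NA_real_, c(n, d))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' Number of windows in a dataset
#' @param ds A `window_dataset`.
#' @return Integer count.
#' @export
n_windows <- function(ds) length(ds$y)

# Subset a window_dataset by index.
ds_subset <- function(ds, idx) {
  out <- ds
  out$X <- ds$X[idx, , , drop = FALSE]
  for (f in c("y", "window_start", "window_end", "site_id", "altitude_band"))
    out[[f]] <- ds[[f]][idx]
  out
}

# Chronological order: window_end, then site_id, then window_start.
chrono_sort <- function(ds) {
  ord <- order(ds$window_end, ds$site_id, ds$window_start)
  ds_subset(ds, ord)
}

#' Fit train-split standardization statistics
#'
#' Per-variable means and standard deviations of the covariates over the
#' training windows' steps only, plus mean/sd of the training targets.
#' Persisting these makes inference-time reuse and inverse transforms
#' possible without touching validation or test rows.
#'
#' @param ds A `window_dataset` (raw scale).
#' @param train_idx Indices of training windows.
#' @return A `standardizer`: list with `mean`, `sd` (per variable) and
#'   `y_mean`, `y_sd`.
#' @export
fit_standardizer <- function(ds, train_idx = seq_len(n_windows(ds))) {
  Xtr <- ds$X[train_idx, , , drop = FALSE]
  d <- dim(Xtr)[3]
  flat <- matrix(Xtr, ncol = d)
  mu <- colMeans(flat)
  sig <- apply(flat, 2, sd)
  if (any(!is.finite(mu)) || any(!is.finite(sig)))
    stop("non-finite standardization statistics")
  if (any(sig == 0))
    stop(sprintf("zero standard deviation for variable '%s'",
                 ds$vars[which(sig == 0)[1]]))
  ytr <- ds$y[train_idx]
  structure(list(mean = setNames(mu, ds$vars), sd = setNames(sig, ds$vars),
                 y_mean = mean(ytr), y_sd = sd(ytr)),
            class = "standardizer")
}

#' Apply (or invert) standardization to a window dataset
#'
#' @param ds A `window_dataset`.
#' @param stats A `standardizer` fitted with [fit_standardizer()].
#' @param invert If `TRUE`, undoes the transform.
#' @return The dataset with `X` z-scored variable-wise (targets are left on
#'   their original scale; training standardizes them internally).
#' @export
apply_standardizer <- function(ds, stats, invert = FALSE) {
  d <- dim(ds$X)[3]
  for (k in seq_len(d)) {
    ds$X[, , k] <- if (invert) ds$X[, , k] * stats$sd[k] + stats$mean[k]
                   else (ds$X[, , k] - stats$mean[k]) / stats$sd[k]
  }
  attr(ds, "standardizer") <- if (invert) NULL else stats
  ds
}

standardize_y <- function(y, stats) (y - stats$y_mean) / stats$y_sd
unstandardize_y <- function(z, stats) z * stats$y_sd + stats$y_mean

#' Assemble the default synthetic benchmark window set
#'
#' Generates the default 104-site, 60-month panel, cleans it, slices
#' 30-month windows and drops the 7 chronologically-last windows so the
#' benchmark holds exactly 3217 samples (104 sites x 31 windows = 3224 - 7).
#'
#' @param config A [scenario_config()]; defaults to the benchmark scenario.
#' @param T_steps Window length (default 30).
#' @param task Target task, as in [make_windows()].
#' @return A list with `panel` (cleaned panel) and `windows`
#'   (a chronologically sorted `window_dataset` of 3217 windows under the
#'   default sizing).
#' @export
benchmark_dataset <- function(config = scenario_config(),
                              T_steps = 30L,
                              task = "restoration_rate") {
  panel <- preprocess_panel(generate_panel(config))
  ds <- make_windows(panel, T_steps = T_steps, task = task)
  n <- n_windows(ds)
  target <- 3217L
  if (n > target && config$n_sites == 104L && config$months == 60L &&
      T_steps == 30L) {
    ds <- ds_subset(ds, seq_len(target))   # drop the chronologically-last 7
  }
  list(panel = panel, windows = ds)
}
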