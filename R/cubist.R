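#' Fit a Cubist/M5-style rule-based regression tree
#'
#' Greedy binary recursive partitioning of the feature space.  At each
#' node the (feature, threshold) pair maximizing the standard-deviation
#' reduction
#' \deqn{SDR = sd(parent) - \sum_c (n_c / n) \, sd(child_c)}
#' is chosen, with candidate thresholds at midpoints of consecutive sorted
#' unique feature values and population (1/n) standard deviations.  Leaves
#' are split best-first until the leaf count reaches `max_rules`, no leaf
#' has `>= 2 * min_leaf` rows, or the best achievable SDR falls below
#' 1e-9.  Each leaf's path becomes one rule region with its own
#' least-squares linear model (ridge fallback, lambda = 1e-6, when the leaf
#' design is rank-deficient); a global linear model over all rows backs up
#' points that fall outside every region.
#'
#' @param X Numeric matrix (n x d), gap-free.
#' @param y Numeric response (length n).
#' @param min_leaf Minimum rows per leaf (default 20).
#' @param max_rules Maximum number of rule regions (default 14).
#' @return A `cubist_model`: ordered rule list (bounds `lo`/`hi` per
#'   feature, coefficients, coverage, region id), global model
#'   coefficients, and training-target statistics used to standardize the
#'   prediction features.
#' @export
cubist_fit <- function(X, y, min_leaf = 20L, max_rules = 14L) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree")
  if (anyNA(X) || anyNA(y)) stop("cubist_fit requires gap-free inputs")
  global_coef <- leaf_ols(X, y)
  y_sd <- sd(y)
  base <- list(rows = seq_len(n),
               lo = rep(-Inf, d), hi = rep(Inf, d))
  leaves <- list(base)
  splittable <- function(leaf) {
    if (length(leaf$rows) < 2L * min_leaf) return(NULL)
    best_split(X, y, leaf$rows, min_leaf)
  }
  if (!is.finite(y_sd) || y_sd == 0 || n < 2L * min_leaf || max_rules <= 1L) {
    # constant response, too few rows, or degenerate tree: one global rule
    rules <- list(make_rule(base, X, y, 1L))
    return(finish_cubist(rules, global_coef, y, d))
  }
  cand <- list(splittable(base))
  while (length(leaves) < max_rules) {
    sdrs <- vapply(cand, function(s) if (is.null(s)) -Inf else s$sdr, 0)
    pick <- which.max(sdrs)
    if (!length(pick) || sdrs[pick] < 1e-9) break
    leaf <- leaves[[pick]]
    sp <- cand[[pick]]
    xk <- X[leaf$rows, sp$feature]
    left <- leaf; right <- leaf
    left$rows <- leaf$rows[xk <= sp$threshold]
    right$rows <- leaf$rows[xk > sp$threshold]
    left$hi[sp$feature] <- min(left$hi[sp$feature], sp$threshold)
    right$lo[sp$feature] <- max(right$lo[sp$feature], sp$threshold)
    leaves[[pick]] <- left
    cand[pick] <- list(splittable(left))     # [<- keeps NULL slots
    leaves[[length(leaves) + 1L]] <- right
    cand[length(cand) + 1L] <- list(splittable(right))
  }
  rules <- lapply(seq_along(leaves), function(j)
    make_rule(leaves[[j]], X, y, j))
  finish_cubist(rules, global_coef, y, d)
}

finish_cubist <- function(rules, global_coef, y, d) {
  structure(list(rules = rules,
                 global_coef = global_coef,
                 y_mean = mean(y),
                 y_sd = if (sd(y) > 0) sd(y) else 1,
                 d = d,
                 version = 1L),
            class = "cubist_model")
}

make_rule <- function(leaf, X, y, region_id) {
  rows <- leaf$rows
  list(lo = leaf$lo, hi = leaf$hi,
       coef = leaf_ols(X[rows, , drop = FALSE], y[rows]),
       coverage = length(rows),
       region_id = region_id)
}

# Least-squares with intercept; ridge fallback (lambda = 1e-6) if the leaf
# design matrix is rank-deficient.
leaf_ols <- function(X, y) {
  A <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(A, y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    lambda <- 1e-6
    beta <- solve(crossprod(A) + diag(lambda, ncol(A)), crossprod(A, y))[, 1]
  }
  unname(beta)
}

pop_sd_prefix <- function(y_sorted) {
  # population sd of y_sorted[1..i] for every prefix i, via running moments
  n <- length(y_sorted)
  s1 <- cumsum(y_sorted)
  s2 <- cumsum(y_sorted^2)
  i <- seq_len(n)
  sqrt(pmax(s2 / i - (s1 / i)^2, 0))
}

# Exhaustive SDR maximization over features and midpoint thresholds.
# Ties resolved by (larger SDR, smaller feature index, smaller threshold).
best_split <- function(X, y, rows, min_leaf) {
  n <- length(rows)
  yv <- y[rows]
  sd_parent <- sqrt(max(mean(yv^2) - mean(yv)^2, 0))
  best <- NULL
  for (k in seq_len(ncol(X))) {
    xk <- X[rows, k]
    ord <- order(xk, method = "radix")
    xs <- xk[ord]
    ys <- yv[ord]
    # split after position i means left = 1..i; valid only between
    # distinct x values and with both children >= min_leaf
    distinct <- which(xs[-n] < xs[-1])
    valid <- distinct[distinct >= min_leaf & (n - distinct) >= min_leaf]
    if (!length(valid)) next
    sdl <- pop_sd_prefix(ys)
    sdr_rev <- pop_sd_prefix(rev(ys))       # suffix sds, reversed order
    sdr_right <- rev(sdr_rev)[-1]           # sd of ys[(i+1)..n] at index i
    i <- valid
    sdr <- sd_parent - (i / n) * sdl[i] - ((n - i) / n) * sdr_right[i]
    j <- which.max(sdr)  # first maximum: smallest threshold wins ties
    thr <- (xs[i[j]] + xs[i[j] + 1]) / 2
    if (is.null(best) || sdr[j] > best$sdr) {
      # strict >: the smallest feature index wins exact ties across features
      best <- list(feature = k, threshold = thr, sdr = sdr[j],
                   sd_parent = sd_parent)
    }
  }
  best
}

# Row indices of the rule matching each row of X (0 = none).
match_rules <- function(model, X) {
  X <- as.matrix(X)
  hit <- integer(nrow(X))
  for (r in model$rules) {
    ok <- rep(TRUE, nrow(X))
    for (k in seq_len(model$d)) {
      if (is.finite(r$lo[k])) ok <- ok & X[, k] > r$lo[k]
      if (is.finite(r$hi[k])) ok <- ok & X[, k] <= r$hi[k]
    }
    hit[ok & hit == 0L] <- r$region_id
  }
  hit
}

#' Predict from a fitted Cubist model
#'
#' Applies the linear model of the unique rule region containing each
#' point; points outside every region (numeric edge cases) fall back to
#' the global linear model.  Threshold boundaries route left
#' (`<=` inclusive).
#'
#' @param object A `cubist_model`.
#' @param newdata Numeric matrix (n x d) or a single d-vector.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.cubist_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$d)
    stop(sprintf("expected %d features, got %d", object$d, ncol(X)))
  hit <- match_rules(object, X)
  A <- cbind(1, X)
  out <- as.numeric(A %*% object$global_coef)
  for (r in object$rules) {
    idx <- hit == r$region_id
    if (any(idx)) out[idx] <- A[idx, , drop = FALSE] %*% r$coef
  }
  out
}

# Rules ranked by training coverage (ties by region id); indices of the
# top `k` region ids, in feature-slot order.
top_rule_ids <- function(model, k) {
  cov <- vapply(model$rules, `[[`, 0, "coverage")
  ids <- vapply(model$rules, `[[`, 0L, "region_id")
  ids[order(-cov, ids)][seq_len(min(k, length(ids)))]
}

#' Structured rule features for the sequence model
#'
#' Maps each input point to the fixed-width feature vector consumed by the
#' temporal layer: activation indicators of the top `m - 2` rules (ranked
#' by training coverage, ties by region id; zero-padded when fewer rules
#' exist), followed by the active rule's local prediction and the global
#' model's prediction, both standardized by the training-target mean/sd.
#'
#' @param model A `cubist_model`.
#' @param X Numeric matrix (n x d) or a single d-vector.
#' @param m Output feature width (default 16).
#' @return An n x m matrix.
#' @export
cubist_rule_features <- function(model, X, m = 16L) {
  if (m < 3) stop("feature_dim must be >= 3")
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  n <- nrow(X)
  keep <- top_rule_ids(model, m - 2L)
  hit <- match_rules(model, X)
  F <- matrix(0, n, m)
  for (s in seq_along(keep)) F[hit == keep[s], s] <- 1
  A <- cbind(1, X)
  global_pred <- as.numeric(A %*% model$global_coef)
  local_pred <- global_pred
  for (r in model$rules) {
    idx <- hit == r$region_id
    if (any(idx)) local_pred[idx] <- A[idx, , drop = FALSE] %*% r$coef
  }
  F[, m - 1L] <- (local_pred - model$y_mean) / model$y_sd
  F[, m] <- (global_pred - model$y_mean) / model$y_sd
  F
}

#' Rule features for every step of every window
#'
#' @param model A `cubist_model`.
#' @param X N x T x d array of (standardized) covariates.
#' @param m Feature width (default 16).
#' @return N x T x m array.
#' @export
cubist_featurize_windows <- function(model, X, m = 16L) {
  dims <- dim(X)
  flat <- matrix(X, nrow = dims[1] * dims[2], ncol = dims[3])
  F <- cubist_rule_features(model, flat, m = m)
  array(F, c(dims[1], dims[2], m))
}

#' Fit the Cubist feature-extraction layer on training windows
#'
#' Flattens the training windows to per-step rows; each step inherits its
#' window's target (the extractor is supervised at step level with the
#' window-level signal).  Inputs are expected on the standardized scale
#' and the target standardized by the training statistics.
#'
#' @param X_train N x T x d array of standardized training covariates.
#' @param y_train Length-N standardized training targets.
#' @param min_leaf,max_rules Passed to [cubist_fit()].
#' @return A `cubist_model`.
#' @export
fit_cubist_layer <- function(X_train, y_train, min_leaf = 20L, max_rules = 14L) {
  dims <- dim(X_train)
  flat <- matrix(X_train, nrow = dims[1] * dims[2], ncol = dims[3])
  y_rep <- rep(y_train, times = dims[2])   # column-major: step-major blocks
  cubist_fit(flat, y_rep, min_leaf = min_leaf, max_rules = max_rules)
}

#' Serialize / restore a Cubist model as versioned JSON
#'
#' @param model A `cubist_model`.
#' @param path File path.
#' @return `path` (write) or the restored `cubist_model` (read).
#' @export
cubist_to_json <- function(model, path) {
  obj <- list(
    format = "vegrestore-cubist",
    version = model$version,
    d = model$d,
    y_mean = model$y_mean,
    y_sd = model$y_sd,
    global_coef = model$global_coef,
    rules = lapply(model$rules, function(r)
      list(lo = r$lo, hi = r$hi, coef = r$coef,
           coverage = r$coverage, region_id = r$region_id))
  )
  # I(17) significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname cubist_to_json
#' @export
cubist_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vegrestore-cubist"))
    stop("not a serialized cubist model")
  rules <- lapply(seq_len(nrow(obj$rules)), function(i)
    list(lo = unlist(obj$rules$lo[i]), hi = unlist(obj$rules$hi[i]),
         coef = unlist(obj$rules$coef[i]),
         coverage = obj$rules$coverage[i],
         region_id = as.integer(obj$rules$region_id[i])))
  structure(list(rules = rules, global_coef = obj$global_coef,
                 y_mean = obj$y_mean, y_sd = obj$y_sd,
                 d = obj$d, version = obj$version),
            class = "cubist_model")
}
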