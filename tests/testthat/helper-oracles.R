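# Independent oracle implementations: deliberately written as plain scalar
# loops / exhaustive searches, sharing no code with the package internals.

# GRU cell per-component scalar transcription of the gate equations.
oracle_gru_cell <- function(x, h_prev, p) {
  hid <- length(h_prev)
  h_new <- numeric(hid)
  for (i in seq_len(hid)) {
    z_i <- 0; r_i <- 0
    for (k in seq_along(x)) {
      z_i <- z_i + p$Wz[i, k] * x[k]
      r_i <- r_i + p$Wr[i, k] * x[k]
    }
    for (k in seq_len(hid)) {
      z_i <- z_i + p$Uz[i, k] * h_prev[k]
      r_i <- r_i + p$Ur[i, k] * h_prev[k]
    }
    z_i <- 1 / (1 + exp(-(z_i + p$bz[i])))
    r_i <- 1 / (1 + exp(-(r_i + p$br[i])))
    # candidate needs the full reset gate vector; recompute it
    cand <- 0
    for (k in seq_along(x)) cand <- cand + p$Wh[i, k] * x[k]
    for (k in seq_len(hid)) {
      r_k <- 0
      for (kk in seq_along(x)) r_k <- r_k + p$Wr[k, kk] * x[kk]
      for (kk in seq_len(hid)) r_k <- r_k + p$Ur[k, kk] * h_prev[kk]
      r_k <- 1 / (1 + exp(-(r_k + p$br[k])))
      cand <- cand + p$Uh[i, k] * (r_k * h_prev[k])
    }
    cand <- tanh(cand + p$bh[i])
    h_new[i] <- (1 - z_i) * h_prev[i] + z_i * cand
  }
  h_new
}

oracle_gru_forward <- function(seq_mat, p) {
  hid <- nrow(p$Wz)
  h <- numeric(hid)
  H <- matrix(NA_real_, nrow(seq_mat), hid)
  for (t in seq_len(nrow(seq_mat))) {
    h <- oracle_gru_cell(seq_mat[t, ], h, p)
    H[t, ] <- h
  }
  H
}

oracle_bigru_layer <- function(seq_mat, fwd, bwd) {
  Hf <- oracle_gru_forward(seq_mat, fwd)
  Hb <- oracle_gru_forward(seq_mat[rev(seq_len(nrow(seq_mat))), , drop = FALSE],
                           bwd)
  cbind(Hf, Hb[rev(seq_len(nrow(seq_mat))), , drop = FALSE])
}

scalar_params <- function(v = 1) {
  list(Wz = matrix(v, 1, 1), Uz = matrix(v, 1, 1), bz = 0,
       Wr = matrix(v, 1, 1), Ur = matrix(v, 1, 1), br = 0,
       Wh = matrix(v, 1, 1), Uh = matrix(v, 1, 1), bh = 0)
}

random_gru_params <- function(input_dim, hidden) {
  m <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(Wz = m(hidden, input_dim), Uz = m(hidden, hidden), bz = rnorm(hidden),
       Wr = m(hidden, input_dim), Ur = m(hidden, hidden), br = rnorm(hidden),
       Wh = m(hidden, input_dim), Uh = m(hidden, hidden), bh = rnorm(hidden))
}

# Exhaustive standard-deviation-reduction split search (population sd),
# looping every feature and every midpoint threshold directly.
oracle_best_split <- function(X, y, min_leaf) {
  sd_pop <- function(v) sqrt(max(mean(v^2) - mean(v)^2, 0))
  n <- nrow(X)
  best <- NULL
  for (k in seq_len(ncol(X))) {
    u <- sort(unique(X[, k]))
    if (length(u) < 2) next
    for (thr in (u[-length(u)] + u[-1]) / 2) {
      left <- X[, k] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      sdr <- sd_pop(y) - (nl / n) * sd_pop(y[left]) - (nr / n) * sd_pop(y[!left])
      if (is.null(best) || sdr > best$sdr) {
        best <- list(feature = k, threshold = thr, sdr = sdr)
      }
    }
  }
  best
}

oracle_softmax <- function(v) exp(v) / sum(exp(v))

# Small, fast scenario for unit tests (not the benchmark conditions).
test_scenario <- function(n_sites = 12L, months = 36L, seed = 101L, ...) {
  scenario_config(n_sites = n_sites, months = months, seed = seed, ...)
}

expect_all_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
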