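sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize GRU cell parameters
#'
#' All weights drawn uniform on `(-1/sqrt(hidden), 1/sqrt(hidden))`;
#' biases zero.  Matrices follow the gate equations: `W_*` map the input,
#' `U_*` map the previous hidden state, for the update gate (z), reset
#' gate (r) and candidate state (h).
#'
#' @param input_dim Input width.
#' @param hidden Hidden width.
#' @return A list `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh` (W: hidden x input,
#'   U: hidden x hidden, b: length hidden).  Uses the current RNG stream.
#' @export
init_gru_params <- function(input_dim, hidden) {
  lim <- 1 / sqrt(hidden)
  mat <- function(r, c) matrix(runif(r * c, -lim, lim), r, c)
  list(Wz = mat(hidden, input_dim), Uz = mat(hidden, hidden),
       bz = numeric(hidden),
       Wr = mat(hidden, input_dim), Ur = mat(hidden, hidden),
       br = numeric(hidden),
       Wh = mat(hidden, input_dim), Uh = mat(hidden, hidden),
       bh = numeric(hidden))
}

#' One GRU cell step
#'
#' Implements the gated update
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)}
#' \deqn{\tilde h_t = \tanh(W_h x_t + U_h (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#'
#' @param x_t Input vector (length input_dim) or batch matrix
#'   (batch x input_dim).
#' @param h_prev Previous hidden state, same leading shape as `x_t`.
#' @param p Parameters from [init_gru_params()].
#' @return New hidden state, same shape as `h_prev`.
#' @export
gru_cell <- function(x_t, h_prev, p) {
  vec <- is.null(dim(x_t))
  X <- if (vec) matrix(x_t, 1) else x_t
  H <- if (vec) matrix(h_prev, 1) else h_prev
  out <- gru_cell_forward(X, H, p)$h
  if (vec) drop(out) else out
}

gru_cell_forward <- function(X, Hprev, p) {
  if (ncol(X) != ncol(p$Wz))
    stop(sprintf("gru_cell: input width %d, expected %d", ncol(X), ncol(p$Wz)))
  if (ncol(Hprev) != nrow(p$Uz))
    stop("gru_cell: hidden width mismatch")
  z <- sigmoid(sweep(X %*% t(p$Wz) + Hprev %*% t(p$Uz), 2, p$bz, `+`))
  r <- sigmoid(sweep(X %*% t(p$Wr) + Hprev %*% t(p$Ur), 2, p$br, `+`))
  rh <- r * Hprev
  c_ <- tanh(sweep(X %*% t(p$Wh) + rh %*% t(p$Uh), 2, p$bh, `+`))
  h <- (1 - z) * Hprev + z * c_
  list(h = h, cache = list(X = X, Hprev = Hprev, z = z, r = r, c = c_, rh = rh))
}

# Backward through one cell step.  dh: gradient wrt h_t (batch x hidden).
# Returns gradients wrt x_t, h_{t-1} and accumulates parameter gradients
# into `acc` (an environment holding arrays named as in the param list).
gru_cell_backward <- function(dh, cache, p, acc) {
  z <- cache$z; r <- cache$r; c_ <- cache$c
  Hprev <- cache$Hprev; X <- cache$X
  dz_pre <- dh * (c_ - Hprev) * z * (1 - z)
  dc_pre <- dh * z * (1 - c_^2)
  dh_prev <- dh * (1 - z)
  drh <- dc_pre %*% p$Uh
  dr_pre <- drh * Hprev * r * (1 - r)
  dh_prev <- dh_prev + drh * r
  dh_prev <- dh_prev + dz_pre %*% p$Uz + dr_pre %*% p$Ur
  dX <- dz_pre %*% p$Wz + dr_pre %*% p$Wr + dc_pre %*% p$Wh
  acc$Wz <- acc$Wz + crossprod(dz_pre, X)
  acc$Uz <- acc$Uz + crossprod(dz_pre, Hprev)
  acc$bz <- acc$bz + colSums(dz_pre)
  acc$Wr <- acc$Wr + crossprod(dr_pre, X)
  acc$Ur <- acc$Ur + crossprod(dr_pre, Hprev)
  acc$br <- acc$br + colSums(dr_pre)
  acc$Wh <- acc$Wh + crossprod(dc_pre, X)
  acc$Uh <- acc$Uh + crossprod(dc_pre, cache$rh)
  acc$bh <- acc$bh + colSums(dc_pre)
  dX_dHprev <- list(dX = dX, dHprev = dh_prev)
  dX_dHprev
}

#' Run a GRU over a sequence
#'
#' Iterates [gru_cell()] over the rows of `seq` from an all-zero initial
#' state and returns every hidden state.
#'
#' @param seq T x input matrix (one sequence).
#' @param p Parameters from [init_gru_params()].
#' @return T x hidden matrix of states.
#' @export
gru_forward <- function(seq, p) {
  if (is.null(dim(seq))) seq <- matrix(seq, ncol = 1)
  if (nrow(seq) < 1) stop("empty sequence")
  X <- array(seq, c(1, nrow(seq), ncol(seq)))
  out <- gru_dir_forward(X, p, reverse = FALSE)
  matrix(out$H[1, , ], nrow(seq), nrow(p$Wz))
}

# Batched directional pass.  X: (batch, T, input).  reverse = TRUE runs the
# recurrence from the last step to the first (states stored at their own
# time positions).  Returns H (batch, T, hidden) and per-step caches.
gru_dir_forward <- function(X, p, reverse = FALSE) {
  b <- dim(X)[1]; Tn <- dim(X)[2]; d_in <- dim(X)[3]
  hid <- nrow(p$Wz)
  H <- array(0, c(b, Tn, hid))
  caches <- vector("list", Tn)
  h <- matrix(0, b, hid)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  for (t in ts) {
    step <- gru_cell_forward(matrix(X[, t, ], b, d_in), h, p)
    h <- step$h
    H[, t, ] <- h
    caches[[t]] <- step$cache
  }
  list(H = H, caches = caches)
}

gru_dir_backward <- function(dH, caches, p, reverse = FALSE) {
  b <- dim(dH)[1]; Tn <- dim(dH)[2]; hid <- dim(dH)[3]
  d_in <- ncol(p$Wz)
  acc <- new.env(parent = emptyenv())
  for (nm in names(p)) assign(nm, p[[nm]] * 0, envir = acc)
  dX <- array(0, c(b, Tn, d_in))
  dh_carry <- matrix(0, b, hid)
  ts <- if (reverse) seq_len(Tn) else rev(seq_len(Tn))
  for (t in ts) {
    dh <- matrix(dH[, t, ], b, hid) + dh_carry
    back <- gru_cell_backward(dh, caches[[t]], p, acc)
    dX[, t, ] <- back$dX
    dh_carry <- back$dHprev
  }
  grads <- mget(names(p), envir = acc)
  list(grads = grads, dX = dX)
}

#' One bidirectional GRU layer
#'
#' Runs a forward-time GRU and a reversed-time GRU over the same sequence
#' and concatenates their states at each step, forward half first:
#' `H_t = [h_fwd_t ; h_bwd_t]`.
#'
#' @param seq T x input matrix.
#' @param fwd,bwd Parameters of the two directions.
#' @return T x (2 * hidden) matrix.
#' @export
bigru_layer <- function(seq, fwd, bwd) {
  if (is.null(dim(seq))) seq <- matrix(seq, ncol = 1)
  X <- array(seq, c(1, nrow(seq), ncol(seq)))
  Hf <- gru_dir_forward(X, fwd, reverse = FALSE)$H
  Hb <- gru_dir_forward(X, bwd, reverse = TRUE)$H
  cbind(matrix(Hf[1, , ], nrow(seq)), matrix(Hb[1, , ], nrow(seq)))
}

#' Stacked (Bi)GRU over one sequence
#'
#' Layer 1 consumes the input features; each further layer consumes the
#' previous layer's concatenated states.  Dropout (inverted scaling) is
#' applied to inter-layer activations only, and only in training mode, so
#' inference is deterministic and needs no rescaling.
#'
#' @param seq T x input matrix.
#' @param layers List of layers; each layer is `list(fwd = , bwd = )`
#'   ( `bwd = NULL` for a unidirectional stack).
#' @param dropout Dropout rate on inter-layer activations.
#' @param training If `TRUE`, applies dropout using the current RNG stream.
#' @return T x (2 * hidden) (or T x hidden if unidirectional) matrix.
#' @export
bigru_stack <- function(seq, layers, dropout = 0, training = FALSE) {
  if (is.null(dim(seq))) seq <- matrix(seq, ncol = 1)
  H <- seq
  for (l in seq_along(layers)) {
    if (l > 1 && training && dropout > 0) {
      mask <- (matrix(runif(length(H)), nrow(H)) >= dropout) / (1 - dropout)
      H <- H * mask
    }
    lay <- layers[[l]]
    H <- if (is.null(lay$bwd)) {
      gru_forward(H, lay$fwd)
    } else {
      bigru_layer(H, lay$fwd, lay$bwd)
    }
  }
  H
}
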