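#' Initialize attention and head parameters
#'
#' Projection matrices uniform on `(-1/sqrt(d_k), 1/sqrt(d_k))`, head
#' weights likewise, bias zero.  Uses the current RNG stream.
#'
#' @param in_dim Width of the temporal representation (2 x hidden for a
#'   BiGRU).
#' @param d_k Projection width (default 64).
#' @return List `Wq, Wk, Wv` (in_dim x d_k), `w` (length d_k), `b`.
#' @export
init_attention_params <- function(in_dim, d_k = 64L) {
  lim <- 1 / sqrt(d_k)
  mat <- function(r, c) matrix(runif(r * c, -lim, lim), r, c)
  list(Wq = mat(in_dim, d_k), Wk = mat(in_dim, d_k), Wv = mat(in_dim, d_k),
       w = runif(d_k, -lim, lim), b = 0)
}

#' Query / key / value projections
#'
#' Plain matrix products `Q = H W_Q`, `K = H W_K`, `V = H W_V` (no bias).
#'
#' @param H T x in_dim matrix of temporal representations.
#' @param p Parameters from [init_attention_params()].
#' @return List of three T x d_k matrices `Q`, `K`, `V`.
#' @export
project_qkv <- function(H, p) {
  if (ncol(H) != nrow(p$Wq))
    stop(sprintf("attention: representation width %d, expected %d",
                 ncol(H), nrow(p$Wq)))
  list(Q = H %*% p$Wq, K = H %*% p$Wk, V = H %*% p$Wv)
}

#' Scaled dot-product attention weights
#'
#' `A = rowsoftmax(Q K' / sqrt(d_k))`; each row is a probability
#' distribution over time steps.
#'
#' @param Q,K T x d_k matrices.
#' @param d_k Scaling width (defaults to `ncol(Q)`).
#' @return T x T row-stochastic matrix.
#' @export
attention_weights <- function(Q, K, d_k = ncol(Q)) {
  S <- Q %*% t(K) / sqrt(d_k)
  if (any(!is.finite(S))) stop("non-finite attention scores")
  row_softmax(S)
}

row_softmax <- function(S) {
  S <- S - apply(S, 1, max)      # shift-invariant, numerically safe
  E <- exp(S)
  E / rowSums(E)
}

#' Weighted fusion of value vectors
#'
#' Computes the per-row contexts `A V`, then fuses them into a single
#' vector by averaging rows.  The per-step importance weights
#' `alpha_t` (used for the critical-moment analysis) are the column means
#' of `A` and sum to 1.
#'
#' @param A T x T row-stochastic attention matrix.
#' @param V T x d_k value matrix.
#' @return List with `context` (length d_k) and `alpha` (length T).
#' @export
attend <- function(A, V) {
  if (any(abs(rowSums(A) - 1) > 1e-6))
    stop("attention matrix rows must sum to 1")
  C <- A %*% V
  list(context = colMeans(C), alpha = colMeans(A))
}

#' Affine regression head
#'
#' @param context Attended feature vector (length d_k).
#' @param p Attention parameters (uses `w` and `b`).
#' @return Scalar prediction on the standardized target scale.
#' @export
predict_head <- function(context, p) {
  as.numeric(sum(p$w * context) + p$b)
}

# Forward through attention + head for one sample.  H: T x in_dim.
attention_forward <- function(H, p) {
  qkv <- project_qkv(H, p)
  A <- attention_weights(qkv$Q, qkv$K, ncol(qkv$Q))
  fused <- attend(A, qkv$V)
  yhat <- predict_head(fused$context, p)
  list(yhat = yhat, cache = list(H = H, Q = qkv$Q, K = qkv$K, V = qkv$V,
                                 A = A, context = fused$context,
                                 alpha = fused$alpha))
}

# Backward for one sample; dy scalar.  Accumulates parameter grads into
# environment `acc` (Wq, Wk, Wv, w, b); returns dH.
attention_backward <- function(dy, cache, p, acc) {
  H <- cache$H; A <- cache$A; V <- cache$V; Q <- cache$Q; K <- cache$K
  Tn <- nrow(H); d_k <- ncol(Q)
  dcontext <- dy * p$w
  acc$w <- acc$w + dy * cache$context
  acc$b <- acc$b + dy
  dC <- matrix(rep(dcontext / Tn, each = Tn), Tn, d_k)  # context = colMeans(A V)
  dA <- dC %*% t(V)
  dV <- crossprod(A, dC)
  # softmax rows: dS_i = A_i * (dA_i - <dA_i, A_i>)
  rowdot <- rowSums(dA * A)
  dS <- A * (dA - rowdot)
  dQ <- dS %*% K / sqrt(d_k)
  dK <- crossprod(dS, Q) / sqrt(d_k)
  acc$Wq <- acc$Wq + crossprod(H, dQ)
  acc$Wk <- acc$Wk + crossprod(H, dK)
  acc$Wv <- acc$Wv + crossprod(H, dV)
  dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
}

# Mean-pool aggregator (ablation without attention): context = colMeans(H).
meanpool_forward <- function(H, p) {
  context <- colMeans(H)
  list(yhat = predict_head(context, p), cache = list(H = H, context = context))
}

meanpool_backward <- function(dy, cache, p, acc) {
  acc$w <- acc$w + dy * cache$context
  acc$b <- acc$b + dy
  Tn <- nrow(cache$H)
  matrix(rep(dy * p$w / Tn, each = Tn), Tn, length(p$w))
}

# Last-state aggregator (unidirectional GRU baseline): context = H[T, ].
last_forward <- function(H, p) {
  context <- H[nrow(H), ]
  list(yhat = predict_head(context, p), cache = list(H = H, context = context))
}

last_backward <- function(dy, cache, p, acc) {
  acc$w <- acc$w + dy * cache$context
  acc$b <- acc$b + dy
  dH <- matrix(0, nrow(cache$H), length(p$w))
  dH[nrow(dH), ] <- dy * p$w
  dH
}
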