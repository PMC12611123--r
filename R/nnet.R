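# Network assembly: stacked (Bi)GRU + aggregator + affine head, with
# hand-written reverse-mode gradients and an Adam optimizer.  Parameters
# live in a nested list so the optimizer can traverse them generically.

#' Sequence-model architecture configuration
#'
#' @param input_dim Per-step input width (16 Cubist features for the full
#'   model, 6 raw covariates for the raw-input ablation).
#' @param hidden Hidden width per direction (default 64).
#' @param n_layers Number of recurrent layers (default 2).
#' @param bidirectional Bidirectional recurrence (default `TRUE`).
#' @param aggregator `"attention"` (scaled dot-product self-attention with
#'   row-averaged fusion), `"mean"` (mean pooling) or `"last"` (final
#'   state).
#' @param d_k Attention projection width (default 64).
#' @param dropout Inter-layer dropout rate (default 0.3).
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim, hidden = 64L, n_layers = 2L,
                         bidirectional = TRUE,
                         aggregator = c("attention", "mean", "last"),
                         d_k = 64L, dropout = 0.3) {
  aggregator <- match.arg(aggregator)
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers),
                 bidirectional = isTRUE(bidirectional),
                 aggregator = aggregator, d_k = as.integer(d_k),
                 dropout = dropout),
            class = "model_config")
}

rep_width <- function(cfg) cfg$hidden * (1L + cfg$bidirectional)

#' Initialize all network parameters
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed (initialization is deterministic given it).
#' @return Nested parameter list (`layers`, `agg`).
#' @export
init_model_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    layers <- vector("list", cfg$n_layers)
    in_dim <- cfg$input_dim
    for (l in seq_len(cfg$n_layers)) {
      layers[[l]] <- list(fwd = init_gru_params(in_dim, cfg$hidden),
                          bwd = if (cfg$bidirectional)
                            init_gru_params(in_dim, cfg$hidden))
      in_dim <- rep_width(cfg)
    }
    agg <- if (cfg$aggregator == "attention") {
      init_attention_params(rep_width(cfg), cfg$d_k)
    } else {
      lim <- 1 / sqrt(rep_width(cfg))
      list(w = runif(rep_width(cfg), -lim, lim), b = 0)
    }
    list(layers = layers, agg = agg)
  })
}

# Forward pass over a batch.  X: (batch, T, input_dim).  Returns
# predictions (standardized target scale) and, when `keep_cache`, all
# intermediates needed for the backward pass.  Dropout masks are drawn
# from the current RNG stream when `training`.
nn_forward <- function(params, cfg, X, training = FALSE, keep_cache = FALSE) {
  b <- dim(X)[1]; Tn <- dim(X)[2]
  inp <- X
  layer_caches <- vector("list", cfg$n_layers)
  masks <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    if (l > 1 && training && cfg$dropout > 0) {
      mask <- array((runif(length(inp)) >= cfg$dropout) / (1 - cfg$dropout),
                    dim(inp))
      inp <- inp * mask
      masks[[l]] <- mask
    }
    lay <- params$layers[[l]]
    f <- gru_dir_forward(inp, lay$fwd, reverse = FALSE)
    if (cfg$bidirectional) {
      bwd <- gru_dir_forward(inp, lay$bwd, reverse = TRUE)
      H <- array(0, c(b, Tn, 2L * cfg$hidden))
      H[, , seq_len(cfg$hidden)] <- f$H
      H[, , cfg$hidden + seq_len(cfg$hidden)] <- bwd$H
      layer_caches[[l]] <- list(f = f$caches, b = bwd$caches)
    } else {
      H <- f$H
      layer_caches[[l]] <- list(f = f$caches, b = NULL)
    }
    inp <- H
  }
  width <- rep_width(cfg)
  agg_fun <- switch(cfg$aggregator, attention = attention_forward,
                    mean = meanpool_forward, last = last_forward)
  yhat <- numeric(b)
  agg_caches <- if (keep_cache) vector("list", b)
  alphas <- if (cfg$aggregator == "attention") matrix(NA_real_, b, Tn)
  for (i in seq_len(b)) {
    Hm <- matrix(inp[i, , ], Tn, width)
    out <- agg_fun(Hm, params$agg)
    yhat[i] <- out$yhat
    if (keep_cache) agg_caches[[i]] <- out$cache
    if (!is.null(alphas) && !is.null(out$cache$alpha))
      alphas[i, ] <- out$cache$alpha
  }
  list(yhat = yhat,
       alpha = alphas,
       cache = if (keep_cache) list(layer_caches = layer_caches,
                                    masks = masks, agg = agg_caches,
                                    b = b, Tn = Tn))
}

# Reverse-mode gradients for nn_forward.  dy: d loss / d yhat, length batch.
nn_backward <- function(params, cfg, cache, dy) {
  b <- cache$b; Tn <- cache$Tn; width <- rep_width(cfg)
  agg_back <- switch(cfg$aggregator, attention = attention_backward,
                     mean = meanpool_backward, last = last_backward)
  acc <- new.env(parent = emptyenv())
  for (nm in names(params$agg)) assign(nm, params$agg[[nm]] * 0, envir = acc)
  dH <- array(0, c(b, Tn, width))
  for (i in seq_len(b)) {
    dH[i, , ] <- agg_back(dy[i], cache$agg[[i]], params$agg, acc)
  }
  agg_grads <- mget(names(params$agg), envir = acc)
  layer_grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lay <- params$layers[[l]]
    lc <- cache$layer_caches[[l]]
    if (cfg$bidirectional) {
      dHf <- dH[, , seq_len(cfg$hidden), drop = FALSE]
      dHb <- dH[, , cfg$hidden + seq_len(cfg$hidden), drop = FALSE]
      back_f <- gru_dir_backward(dHf, lc$f, lay$fwd, reverse = FALSE)
      back_b <- gru_dir_backward(dHb, lc$b, lay$bwd, reverse = TRUE)
      dX <- back_f$dX + back_b$dX
      layer_grads[[l]] <- list(fwd = back_f$grads, bwd = back_b$grads)
    } else {
      back_f <- gru_dir_backward(dH, lc$f, lay$fwd, reverse = FALSE)
      dX <- back_f$dX
      layer_grads[[l]] <- list(fwd = back_f$grads, bwd = NULL)
    }
    if (l > 1 && !is.null(cache$masks[[l]])) dX <- dX * cache$masks[[l]]
    dH <- dX
  }
  list(layers = layer_grads, agg = agg_grads, dX = dH)
}

# --- generic nested-list numerics for the optimizer ---------------------

nmap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) nmap2(f, x, y), a, b)
    out
  } else if (is.null(a)) NULL else f(a, b)
}

nmap3 <- function(f, a, b, c) {
  if (is.list(a)) Map(function(x, y, z) nmap3(f, x, y, z), a, b, c)
  else if (is.null(a)) NULL else f(a, b, c)
}

nsum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) nsum(f, x), 0))
  else if (is.null(a)) 0 else f(a)
}

nzero <- function(a) if (is.list(a)) lapply(a, nzero) else if (is.null(a)) NULL else a * 0

adam_init <- function(params) {
  list(m = nzero(params), v = nzero(params), t = 0L)
}

# One Adam step with global-norm gradient clipping (max norm 5).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 5) {
  gnorm <- sqrt(nsum(function(g) sum(g^2), grads))
  if (is.finite(gnorm) && gnorm > clip_norm)
    grads <- nmap2(function(g, .) g * (clip_norm / gnorm), grads, grads)
  state$t <- state$t + 1L
  state$m <- nmap2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nmap2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  params <- nmap3(function(p, m, v)
    p - lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# Predictions (standardized scale) in memory-bounded chunks.
nn_predict <- function(params, cfg, X, chunk = 256L) {
  n <- dim(X)[1]
  out <- numeric(n)
  alpha <- NULL
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + chunk - 1L, n)
    fw <- nn_forward(params, cfg, X[idx, , , drop = FALSE], training = FALSE)
    out[idx] <- fw$yhat
    if (!is.null(fw$alpha)) {
      if (is.null(alpha)) alpha <- matrix(NA_real_, n, ncol(fw$alpha))
      alpha[idx, ] <- fw$alpha
    }
    at <- at + chunk
  }
  list(yhat = out, alpha = alpha)
}

# Train by minimizing mean-squared error on standardized targets with Adam,
# early stopping on validation loss (min improvement 1e-6, patience
# epochs), best-epoch weight restoration.
nn_train <- function(X_train, y_train, X_val, y_val, cfg,
                     lr = 1e-3, batch_size = 32L, max_epochs = 100L,
                     patience = 10L, min_delta = 1e-6, seed = 1L,
                     verbose = FALSE) {
  params <- init_model_params(cfg, seed = derive_seed(seed, "init"))
  state <- adam_init(params)
  n <- dim(X_train)[1]
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  wait <- 0L
  with_seed(derive_seed(seed, "batches"), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X_train[idx, , , drop = FALSE]
        yb <- y_train[idx]
        fw <- nn_forward(params, cfg, Xb, training = TRUE, keep_cache = TRUE)
        resid <- fw$yhat - yb
        if (any(!is.finite(resid)) || !is.finite(sum(resid^2)))
          stop("training diverged: non-finite loss; lower the learning rate")
        tot <- tot + sum(resid^2)
        dy <- 2 * resid / length(idx)
        grads <- nn_backward(params, cfg, fw$cache, dy)[c("layers", "agg")]
        upd <- adam_step(params, grads, state, lr = lr)
        params <- upd$params
        state <- upd$state
      }
      val_loss <- mean((nn_predict(params, cfg, X_val)$yhat - y_val)^2)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot / n,
                                     val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tot / n, val_loss))
      if (val_loss < best$loss - min_delta) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  list(params = best$params, history = hist,
       best_epoch = best$epoch, stopped_epoch = nrow(hist))
}
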