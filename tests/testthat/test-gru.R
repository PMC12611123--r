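test_that("the gate equations reproduce hand-computed values", {
  # all-zero parameters: z = 0.5, candidate = 0, so h stays at 0
  p0 <- scalar_params(0)
  expect_equal(gru_cell(1.7, 0, p0), 0)
  # scalar case x = 1, h_prev = 0.5, all weights 1, biases 0
  p1 <- scalar_params(1)
  sig <- function(a) 1 / (1 + exp(-a))
  z <- sig(1 + 0.5)
  cand <- tanh(1 + z * 0.5)      # r equals z here
  h_expected <- (1 - z) * 0.5 + z * cand
  expect_equal(gru_cell(1, 0.5, p1), h_expected, tolerance = 1e-12)
  expect_equal(z, 0.81757, tolerance = 1e-5)
  expect_equal(h_expected, 0.8164, tolerance = 5e-4)
  # independent scalar-loop oracle agrees on random vector instances
  set.seed(21)
  for (i in 1:20) {
    p <- random_gru_params(3, 4)
    x <- rnorm(3); h <- rnorm(4)
    expect_all_equal(gru_cell(x, h, p), oracle_gru_cell(x, h, p), 1e-12)
  }
})

test_that("each hidden unit stays between its previous and candidate state", {
  set.seed(22)
  for (i in 1:50) {
    p <- random_gru_params(2, 3)
    x <- rnorm(2, sd = 2); h <- rnorm(3, sd = 2)
    fw <- vegrestore:::gru_cell_forward(matrix(x, 1), matrix(h, 1), p)
    z <- fw$cache$z; r <- fw$cache$r; cand <- fw$cache$c
    expect_true(all(z > 0 & z < 1))
    expect_true(all(r > 0 & r < 1))
    expect_true(all(cand > -1 & cand < 1))
    lo <- pmin(h, as.numeric(cand)); hi <- pmax(h, as.numeric(cand))
    expect_true(all(fw$h >= lo - 1e-12 & fw$h <= hi + 1e-12))
  }
})

test_that("sequence unrolling matches the chained cell and the oracle", {
  p1 <- scalar_params(1)
  x <- matrix(c(1, -0.5, 0.25), ncol = 1)
  H <- gru_forward(x, p1)
  # hand-chain the scalar oracle
  h <- 0
  for (t in 1:3) h <- oracle_gru_cell(x[t, ], h, p1)
  expect_equal(H[3, ], h, tolerance = 1e-12)
  expect_equal(H[1, ], gru_cell(1, 0, p1), tolerance = 1e-12)
  expect_equal(gru_forward(matrix(2.2), p1)[1, ], gru_cell(2.2, 0, p1))
  expect_true(all(gru_forward(x, scalar_params(0)) == 0))
  expect_error(gru_forward(matrix(numeric(0), 0, 1), p1), "empty")
})

test_that("bidirectional composition concatenates forward then backward states", {
  set.seed(23)
  fwd <- random_gru_params(2, 3)
  bwd <- random_gru_params(2, 3)
  x <- matrix(rnorm(10), 5, 2)
  H <- bigru_layer(x, fwd, bwd)
  expect_identical(dim(H), c(5L, 6L))
  expect_all_equal(H, oracle_bigru_layer(x, fwd, bwd), 1e-12)
  # palindromic input with shared parameters: forward half at t equals
  # backward half at T + 1 - t
  pal <- rbind(x[1:2, ], x[2:1, ])
  Hp <- bigru_layer(pal, fwd, fwd)
  for (t in 1:4) {
    expect_all_equal(Hp[t, 1:3], Hp[4 + 1 - t, 4:6], 1e-12)
  }
  # reversing the input (with direction parameters swapped) reverses and
  # swaps the two halves
  Hr <- bigru_layer(x[5:1, ], bwd, fwd)
  expect_all_equal(Hr[5:1, c(4:6, 1:3)], H, 1e-12)
})

test_that("the batched implementation matches the reference over 100 trials", {
  set.seed(24)
  worst <- 0
  for (i in 1:100) {
    d_in <- sample(1:4, 1); hid <- sample(1:5, 1); Tn <- sample(2:7, 1)
    fwd <- random_gru_params(d_in, hid)
    bwd <- random_gru_params(d_in, hid)
    x <- matrix(rnorm(Tn * d_in), Tn, d_in)
    worst <- max(worst, max(abs(bigru_layer(x, fwd, bwd) -
                                  oracle_bigru_layer(x, fwd, bwd))))
  }
  expect_lt(worst, 1e-5)
})

test_that("dropout is confined to training mode between layers", {
  set.seed(25)
  layers <- list(list(fwd = random_gru_params(2, 3),
                      bwd = random_gru_params(2, 3)),
                 list(fwd = random_gru_params(6, 3),
                      bwd = random_gru_params(6, 3)))
  x <- matrix(rnorm(8), 4, 2)
  # no dropout: training and inference agree
  expect_identical(bigru_stack(x, layers, dropout = 0, training = TRUE),
                   bigru_stack(x, layers, dropout = 0, training = FALSE))
  # inference is deterministic regardless of the rate
  h1 <- bigru_stack(x, layers, dropout = 0.3, training = FALSE)
  h2 <- bigru_stack(x, layers, dropout = 0.3, training = FALSE)
  expect_identical(h1, h2)
  # inverted scaling: dropped inter-layer activations are unbiased
  cfg <- model_config(2, hidden = 3, n_layers = 2, bidirectional = TRUE,
                      aggregator = "mean", dropout = 0.4)
  params <- init_model_params(cfg, seed = 3L)
  Xb <- array(rnorm(1 * 3 * 2), c(1, 3, 2))
  base <- nn_forward(params, cfg, Xb, training = FALSE)$yhat
  draws <- replicate(10000, nn_forward(params, cfg, Xb, training = TRUE)$yhat)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - base), 4 * mc_se + 1e-3)
})

test_that("analytic gradients match finite differences", {
  getp <- function(x, pp) { for (k in pp) x <- x[[k]]; x }
  setp <- function(x, pp, v) {
    if (length(pp) == 1) { x[[pp[[1]]]] <- v; x }
    else { x[[pp[[1]]]] <- setp(x[[pp[[1]]]], pp[-1], v); x }
  }
  set.seed(26)
  for (case in list(list(bi = TRUE, agg = "attention"),
                    list(bi = FALSE, agg = "last"),
                    list(bi = TRUE, agg = "mean"))) {
    cfg <- model_config(3, hidden = 4, n_layers = 2, bidirectional = case$bi,
                        aggregator = case$agg, d_k = 5, dropout = 0)
    params <- init_model_params(cfg, seed = 31L)
    X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
    y <- rnorm(2)
    loss <- function(par) mean((nn_forward(par, cfg, X)$yhat - y)^2)
    fw <- nn_forward(params, cfg, X, keep_cache = TRUE)
    gr <- vegrestore:::nn_backward(params, cfg, fw$cache,
                                   2 * (fw$yhat - y) / 2)
    paths <- list(list("layers", 1, "fwd", "Wz"),
                  list("layers", 1, "fwd", "Uh"),
                  list("layers", 2, "fwd", "Wr"),
                  list("agg", "w"))
    if (case$bi) paths <- c(paths, list(list("layers", 2, "bwd", "bh")))
    if (case$agg == "attention")
      paths <- c(paths, list(list("agg", "Wq"), list("agg", "Wv")))
    for (pp in paths) {
      v <- getp(params, pp); g <- getp(gr, pp)
      for (idx in unique(c(1L, length(v)))) {
        eps <- 1e-5
        vp <- v; vp[idx] <- vp[idx] + eps
        vm <- v; vm[idx] <- vm[idx] - eps
        num <- (loss(setp(params, pp, vp)) - loss(setp(params, pp, vm))) /
          (2 * eps)
        expect_lt(abs(num - g[idx]) / max(abs(num) + abs(g[idx]), 1e-6), 1e-4)
      }
    }
  }
})
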