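predict_global <- function(m, x) as.numeric(c(1, x) %*% m$global_coef)

test_that("the 4-point instance splits at 2.5 with exact leaf models", {
  X <- matrix(c(1, 2, 3, 4), 4)
  y <- c(1, 2, 10, 11)
  m <- cubist_fit(X, y, min_leaf = 1L, max_rules = 2L)
  expect_length(m$rules, 2L)
  expect_equal(m$rules[[1]]$hi, 2.5)
  expect_equal(m$rules[[1]]$coef, c(0, 1), tolerance = 1e-10)
  expect_equal(m$rules[[2]]$coef, c(7, 1), tolerance = 1e-10)
  expect_equal(predict(m, 3.5), 10.5, tolerance = 1e-10)
  expect_equal(predict(m, 1.5), 1.5, tolerance = 1e-10)
  # boundary value routes left (<= inclusive)
  expect_equal(predict(m, 2.5), 2.5, tolerance = 1e-10)
})

test_that("degenerate fits collapse to sensible single-rule models", {
  X <- matrix(runif(20), 20)
  m <- cubist_fit(X, rep(5, 20), min_leaf = 2L)
  expect_length(m$rules, 1L)
  expect_equal(predict(m, 0.3), 5, tolerance = 1e-10)
  # max_rules = 1 equals the global OLS model
  set.seed(5)
  X2 <- matrix(rnorm(60), 30, 2)
  y2 <- 1 + X2 %*% c(2, -1) + rnorm(30, sd = 0.1)
  m1 <- cubist_fit(X2, as.numeric(y2), min_leaf = 2L, max_rules = 1L)
  ols <- unname(coef(lm(y2 ~ X2)))
  grid <- matrix(rnorm(20), 10, 2)
  expect_all_equal(predict(m1, grid),
                   cbind(1, grid) %*% ols, 1e-10)
})

test_that("greedy splits equal an exhaustive SDR search", {
  set.seed(42)
  for (trial in 1:30) {
    n <- sample(30:200, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n) + X[, 1]^2
    min_leaf <- sample(c(2L, 5L, 10L), 1)
    mine <- vegrestore:::best_split(X, y, seq_len(n), min_leaf)
    oracle <- oracle_best_split(X, y, min_leaf)
    expect_equal(mine$feature, oracle$feature)
    expect_equal(mine$threshold, oracle$threshold, tolerance = 1e-12)
    expect_equal(mine$sdr, oracle$sdr, tolerance = 1e-12)
    # and at one child node
    left <- which(X[, mine$feature] <= mine$threshold)
    if (length(left) >= 2 * min_leaf) {
      m2 <- vegrestore:::best_split(X, y, left, min_leaf)
      o2 <- oracle_best_split(X[left, , drop = FALSE], y[left], min_leaf)
      if (!is.null(m2) && !is.null(o2)) {
        expect_equal(m2$feature, o2$feature)
        expect_equal(m2$threshold, o2$threshold, tolerance = 1e-12)
      }
    }
  }
})

test_that("fitting is invariant to row order and monotone in rule budget", {
  set.seed(7)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 1] * 2 + sin(X[, 2]) + rnorm(100, sd = 0.2)
  m <- cubist_fit(X, y, min_leaf = 5L, max_rules = 8L)
  perm <- sample(100)
  m_perm <- cubist_fit(X[perm, ], y[perm], min_leaf = 5L, max_rules = 8L)
  grid <- matrix(rnorm(60), 20, 3)
  expect_all_equal(predict(m, grid), predict(m_perm, grid), 1e-10)
  rmse <- function(mod) sqrt(mean((predict(mod, X) - y)^2))
  m1 <- cubist_fit(X, y, min_leaf = 5L, max_rules = 1L)
  expect_lte(rmse(m), rmse(m1))
})

test_that("rule regions partition the training space", {
  set.seed(8)
  X <- matrix(rnorm(400), 100, 4)
  y <- X[, 1] - X[, 3]^2 + rnorm(100, sd = 0.3)
  m <- cubist_fit(X, y, min_leaf = 5L, max_rules = 10L)
  hit <- vegrestore:::match_rules(m, X)
  expect_true(all(hit >= 1))  # every training row matched by exactly one rule
  cov <- vapply(m$rules, `[[`, 0, "coverage")
  ids <- vapply(m$rules, function(r) as.integer(r$region_id), 0L)
  expect_equal(sum(cov), 100)
  expect_equal(as.integer(table(factor(hit, levels = ids))), as.integer(cov))
})

test_that("rule features expose indicators plus standardized predictions", {
  X <- matrix(c(1, 2, 3, 4), 4)
  y <- c(1, 2, 10, 11)
  m <- cubist_fit(X, y, min_leaf = 1L, max_rules = 2L)
  F <- cubist_rule_features(m, 3.5, m = 4L)
  expect_identical(dim(F), c(1L, 4L))
  expect_equal(F[1, 1:2], c(0, 1))  # rule 2 active (ties broken by id)
  expect_equal(F[1, 3], (10.5 - m$y_mean) / m$y_sd, tolerance = 1e-10)
  expect_equal(F[1, 4],
               (predict_global(m, 3.5) - m$y_mean) / m$y_sd,
               tolerance = 1e-10)
  # indicator block sums to at most 1; zero-padding beyond the rule count
  set.seed(9)
  G <- cubist_rule_features(m, matrix(rnorm(50), 50, 1), m = 6L)
  expect_true(all(rowSums(G[, 1:4]) %in% c(0, 1)))
  expect_true(all(G[, 3:4] == 0))  # only 2 rules exist for 4 slots
  expect_error(cubist_rule_features(m, 1, m = 2L), "feature_dim")
})

test_that("window featurization is shape-stable and per-row independent", {
  set.seed(10)
  X <- matrix(rnorm(200), 100, 2)
  y <- X[, 1] + rnorm(100, 0.2)
  m <- cubist_fit(X, y, min_leaf = 5L, max_rules = 4L)
  W <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  F <- cubist_featurize_windows(m, W, m = 6L)
  expect_identical(dim(F), c(5L, 3L, 6L))
  expect_true(all(is.finite(F)))
  perm <- c(3, 1, 5, 2, 4)
  F_perm <- cubist_featurize_windows(m, W[perm, , , drop = FALSE], m = 6L)
  expect_equal(F_perm, F[perm, , , drop = FALSE], tolerance = 1e-12)
  # prediction slots reproduce predict() on the flattened rows
  flat <- matrix(W, 15, 2)
  expect_all_equal(as.vector(F[, , 5]),
                   (predict(m, flat) - m$y_mean) / m$y_sd, 1e-10)
})

test_that("the cubist layer trains on window-broadcast per-step targets", {
  set.seed(11)
  Xw <- array(rnorm(10 * 30 * 2), c(10, 30, 2))
  yw <- rnorm(10)
  m <- fit_cubist_layer(Xw, yw, min_leaf = 5L, max_rules = 6L)
  expect_identical(sum(vapply(m$rules, `[[`, 0, "coverage")), 300)
  m2 <- fit_cubist_layer(Xw, yw, min_leaf = 5L, max_rules = 6L)
  expect_identical(m, m2)
})

test_that("JSON serialization round-trips predictions bit for bit", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 1] * 3 + abs(X[, 2]) + rnorm(100, sd = 0.2)
  m <- cubist_fit(X, y, min_leaf = 5L, max_rules = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  cubist_to_json(m, path)
  back <- cubist_from_json(path)
  grid <- matrix(rnorm(90), 30, 3)
  expect_identical(predict(back, grid), predict(m, grid))
  expect_identical(cubist_rule_features(back, grid),
                   cubist_rule_features(m, grid))
})
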