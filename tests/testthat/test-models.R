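# Dynamic model families: embedding, nu-SVR training, free-run simulation,
# correlation scoring and grid search.

test_that("embedding produces the documented row/feature counts", {
  p <- 1:10; v <- 101:110
  e1 <- embed_signals(p, v, n_p = 2, n_v = 0)
  expect_equal(dim(e1$X), c(8, 3))
  e2 <- embed_signals(p, v, n_p = 2, n_v = 3)
  expect_equal(dim(e2$X), c(7, 6))
  expect_error(embed_signals(1:5, 1:6, 1, 0), "alignment")
})

test_that("embedded rows reproduce the raw samples exactly", {
  set.seed(21)
  p <- rnorm(50); v <- rnorm(50)
  e <- embed_signals(p, v, n_p = 3, n_v = 2)
  for (r in sample(nrow(e$X), 5)) {
    n <- max(3, 2) + r   # original index of row r
    expect_identical(e$X[r, ], c(v_lag1 = v[n - 1], v_lag2 = v[n - 2],
                                 p_lag0 = p[n], p_lag1 = p[n - 1],
                                 p_lag2 = p[n - 2], p_lag3 = p[n - 3]))
    expect_identical(e$y[r], v[n])
  }
})

test_that("linear FIR recovers a realizable 2-tap system to high accuracy", {
  set.seed(22)
  p <- rnorm(300)
  v <- 0.8 * p + 0.2 * c(0, p[-300])
  spec <- model_spec("fir", n_p = 1, C = 1024, nu = 0.9)
  m <- train_model(p, v, spec, dt = 0.4)
  os <- one_step_predict(m, p, v)
  expect_lt(sqrt(mean((os$pred - os$target)^2)), 1e-3)
  # FIR free run has no feedback: identical to one-step output
  fr <- free_run_predict(m, p)
  expect_equal(as.numeric(fr), os$pred, tolerance = 1e-12)
  expect_length(fr, 300 - 1)
})

test_that("training is deterministic and respects the nu-property", {
  set.seed(23)
  p <- rnorm(200)
  v <- tanh(0.7 * p + 0.3 * c(0, p[-200])) + rnorm(200, sd = 0.05)
  spec <- model_spec("narx", n_p = 2, n_v = 1, C = 16, nu = 0.5, sigma = 2)
  m1 <- train_model(p, v, spec, dt = 0.4)
  m2 <- train_model(p, v, spec, dt = 0.4)
  pr1 <- free_run_predict(m1, p, v_init = tail(v, 1))
  pr2 <- free_run_predict(m2, p, v_init = tail(v, 1))
  expect_identical(as.numeric(pr1), as.numeric(pr2))
  # nu lower-bounds the support-vector fraction
  l <- nrow(m1$fit$SV)
  expect_gte(l / (200 - 2), 0.5 - 1e-9)
  expect_error(train_model(p, rep(1, 200), spec, dt = 0.4), "degenerate")
})

test_that("NARX free run tracks a realizable recursion", {
  # true system: v(n) = 0.6 v(n-1) + 0.4 p(n), simulated as the oracle
  set.seed(24)
  p <- as.numeric(arima.sim(list(ar = 0.8), 400)) / 3
  v <- numeric(400)
  for (n in 2:400) v[n] <- 0.6 * v[n - 1] + 0.4 * p[n]
  spec <- model_spec("arx", n_p = 0, n_v = 1, C = 1024, nu = 0.9)
  m <- train_model(p[1:300], v[1:300], spec, dt = 0.4)
  fr <- free_run_predict(m, p[301:400], v_init = v[300])
  expect_false(isTRUE(attr(fr, "diverged")))
  expect_lt(sqrt(mean((as.numeric(fr) - v[301:400])^2)), 1e-2)
  expect_length(fr, 100)
  expect_error(free_run_predict(m, numeric(0)), "length error")
})

test_that("pearson_cc matches the closed-form value and its symmetries", {
  v <- c(1, 2, 3, 4); vh <- c(1, 2, 2, 4)
  # direct formula, computed independently of stats::cor
  num <- sum((v - mean(v)) * (vh - mean(vh)))
  den <- sqrt(sum((v - mean(v))^2) * sum((vh - mean(vh))^2))
  expect_equal(pearson_cc(v, vh), num / den, tolerance = 1e-12)
  expect_equal(pearson_cc(v, v), 1)
  expect_equal(pearson_cc(v, -v), -1)
  expect_error(pearson_cc(v, rep(1, 4)), "constant")
  expect_error(pearson_cc(v, c(1, 2)), "unequal")
})

test_that("grid search is exhaustive, deterministic and order-aware", {
  set.seed(25)
  # realizable linear system with known orders n_p = 1, n_v = 1
  p <- as.numeric(arima.sim(list(ar = 0.7), 240)) / 3
  v <- numeric(240)
  for (n in 2:240) v[n] <- 0.5 * v[n - 1] + 0.3 * p[n] + 0.15 * p[n - 1]
  ps <- uniform_signal(p, 0.4); vs <- uniform_signal(v, 0.4)
  grid <- list(n_p = c(1L, 3L), n_v = c(1L, 3L), C = 2^c(4, 8), nu = 0.7,
               sigma = 1)
  gs <- grid_search(ps, vs, "arx", grid)
  expect_equal(gs$n_evaluated, 2 * 2 * 2)
  expect_equal(nrow(gs$results), 8)
  # true orders are within the CC-maximizing set: best model attains
  # (numerically) the top validation CC achieved at the true orders
  cc_true <- max(gs$results$cc_val[gs$results$n_p == 1 & gs$results$n_v == 1])
  expect_gte(gs$cc_val, cc_true - 1e-9)
  # singleton grid returns that model
  g1 <- list(n_p = 2L, n_v = 1L, C = 16, nu = 0.5, sigma = 1)
  gs1 <- grid_search(ps, vs, "arx", g1)
  expect_equal(gs1$n_evaluated, 1)
  expect_equal(gs1$model$spec$n_p, 2L)
  expect_error(grid_search(ps, vs, "arx", list(n_p = integer(0), n_v = 1L,
                                               C = 1, nu = 0.5, sigma = 1)),
               "empty grid")
})

test_that("nonlinear families nest linear behaviour on linear data", {
  set.seed(26)
  p <- as.numeric(arima.sim(list(ar = 0.7), 300)) / 3
  v <- 0.8 * p + 0.2 * c(0, p[-300]) + rnorm(300, sd = 0.02)
  ps <- uniform_signal(p, 0.4); vs <- uniform_signal(v, 0.4)
  g_lin <- list(n_p = c(1L, 2L), n_v = 0L, C = 2^c(2, 6), nu = 0.5, sigma = 1)
  g_nl <- list(n_p = c(1L, 2L), n_v = 0L, C = 2^c(2, 6), nu = 0.5,
               sigma = 2^c(1, 3, 5))
  cc_fir <- grid_search(ps, vs, "fir", g_lin)$cc_val
  cc_nfir <- grid_search(ps, vs, "nfir", g_nl)$cc_val
  expect_gte(cc_nfir, cc_fir - 0.02)
})

test_that("half/half split is exact in duration", {
  p <- uniform_signal(rnorm(100), 0.4)
  v <- uniform_signal(rnorm(100), 0.4)
  sp <- dcaflow:::split_halves(p, v)
  expect_length(sp$p_train$values, 50)
  expect_length(sp$p_val$values, 50)
  expect_equal(sp$p_val$t0 - sp$p_train$t0, 50 * 0.4)
})

test_that("model specs validate family/order/kernel consistency", {
  expect_error(model_spec("fir", 2, n_v = 1), "n_v = 0")
  expect_error(model_spec("narx", 2, n_v = 0), "n_v >= 1")
  expect_error(model_spec("narx", 2, n_v = 1, nu = 1.2), "nu")
  expect_equal(model_spec("arx", 2, 1)$kernel, "linear")
  expect_equal(model_spec("nfir", 2)$kernel, "gaussian")
})
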