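test_that("PLS recovers a noiseless rank-1 system with one factor", {
  set.seed(31)
  conc <- runif(12, 0.1, 2)
  p <- exp(-((1:50) - 25)^2 / 40)
  X <- outer(conc, p)
  m <- pls_fit(X, conc, 1)
  expect_lt(rmse(conc, pls_predict(m, X)), 1e-8)
})

test_that("full-rank PLS equals ordinary least squares (normal equations)", {
  set.seed(32)
  X <- matrix(rnorm(10 * 5), 10)
  y <- rnorm(10)
  m <- pls_fit(X, y, 5)
  Xc <- scale(X, scale = FALSE)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(m$regression_vector, drop(b_ols), tolerance = 1e-6)
  expect_equal(pls_predict(m, X), drop(Xc %*% b_ols) + mean(y),
               tolerance = 1e-6)
})

test_that("regression vector permutes with the variables", {
  set.seed(33)
  X <- matrix(rnorm(15 * 8), 15)
  y <- rnorm(15)
  m <- pls_fit(X, y, 3)
  perm <- sample(8)
  mp <- pls_fit(X[, perm], y, 3)
  expect_equal(mp$regression_vector, m$regression_vector[perm],
               tolerance = 1e-10)
})

test_that("prediction matches the independent score-space computation", {
  set.seed(34)
  X <- matrix(rnorm(5 * 7), 5)
  y <- rnorm(5)
  m <- pls_fit(X, y, 3)
  f <- nipals_r(X, y, 3)            # plain-R factor-by-factor oracle
  expect_equal(pls_predict(m, X), drop(f$scores %*% f$Q) + mean(y),
               tolerance = 1e-8)
  # prediction is affine in the spectrum
  x0 <- X[1, ]
  a <- c(0.5, 1, 2, 3)
  preds <- vapply(a, function(s) pls_predict(m, s * x0), 0)
  expect_equal(diff(preds, lag = 1) / diff(a),
               rep((preds[2] - preds[1]) / (a[2] - a[1]), 3))
  # mean calibration spectrum predicts the mean response
  expect_equal(pls_predict(m, colMeans(X)), mean(y))
  expect_error(pls_predict(m, matrix(0, 1, 99)), "columns")
})

test_that("rmse and r_squared match their defining formulas", {
  expect_equal(rmse(c(1, 2), c(2, 1)), 1)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(35)
  a <- rnorm(20); b <- rnorm(20)
  s <- 0; for (i in 1:20) s <- s + (a[i] - b[i])^2   # direct summation
  expect_equal(rmse(a, b), sqrt(s / 20))
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, rep(mean(a), 20)), 0)
  y <- c(1, 2, 3, 4, 5); yh <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  expect_equal(r_squared(y, yh), 1 - sum((y - yh)^2) / sum((y - 3)^2))
  expect_error(r_squared(rep(1, 5), y), "constant")
})

test_that("leave-one-out CV equals explicit per-fold refits", {
  set.seed(36)
  X <- matrix(rnorm(4 * 6), 4)
  y <- rnorm(4)
  cv <- loo_cv(X, y, 2)
  oracle <- loo_press_r(X, y, 2)    # 4 manual refits per factor count
  expect_equal(cv$press, oracle$press, tolerance = 1e-8)
  expect_equal(cv$predictions, oracle$predictions, tolerance = 1e-8)
  expect_equal(cv$rmsecv, sqrt(oracle$press / 4), tolerance = 1e-8)
  expect_error(loo_cv(X, y, 3), "exceeds")

  # duplicated rows: still equals the oracle recomputation
  Xd <- rbind(X, X); yd <- c(y, y)
  cvd <- loo_cv(Xd, yd, 3)
  od <- loo_press_r(Xd, yd, 3)
  expect_equal(cvd$press, od$press, tolerance = 1e-8)

  # noiseless rank-1 data: PRESS(1) ~ 0 and one factor chosen
  conc <- runif(8, 0.5, 2)
  X1 <- outer(conc, exp(-((1:30) - 10)^2 / 30))
  cv1 <- loo_cv(X1, conc, 3)
  expect_lt(cv1$press[1], 1e-12)
  expect_identical(cv1$chosen, 1L)
})

test_that("NIPALS scores are orthogonal and RMSEC never increases with factors", {
  set.seed(37)
  X <- matrix(rnorm(25 * 40), 25)
  y <- rnorm(25)
  m <- pls_fit(X, y, 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / min(diag(G)), 1e-8)
  rmsec <- vapply(1:6, function(a) {
    rmse(y, pls_predict(pls_fit(X, y, a), X))
  }, 0)
  expect_true(all(diff(rmsec) <= 1e-12))
})

test_that("on noisy synthetic data the chosen factor count sits near m + 1", {
  hits <- 0
  for (s in 1:20) {
    cfg <- generator_config(grid = make_grid(800, 2200, 5))
    sim <- simulate_dataset(cfg, seed = 400 + s)
    al <- align_dataset(sim$dataset, sim$references, "glycyrrhizic_acid")
    cv <- loo_cv(al$X, al$c, 8)
    if (cv$chosen >= 4 && cv$chosen <= 7) hits <- hits + 1
  }
  expect_gte(hits, 15)   # m = 4 analytes + water: minimum near m..m+3
})

test_that("evaluate_model reports the metric suite consistently", {
  set.seed(38)
  cfg <- small_config()
  sim <- simulate_dataset(cfg, seed = 39)
  al <- align_dataset(sim$dataset, sim$references, "total_flavonoids")
  sp <- ks_split(al$X, 2 / 3)
  Xc <- al$X[sp$calibration_idx, ]; cc <- al$c[sp$calibration_idx]
  Xv <- al$X[sp$validation_idx, ]; cv_ <- al$c[sp$validation_idx]
  m <- pls_fit(Xc, cc, 5)
  met <- evaluate_model(m, Xc, cc, Xv, cv_)
  expect_equal(met$rmsec, rmse(cc, pls_predict(m, Xc)))
  expect_equal(met$rmsep, rmse(cv_, pls_predict(m, Xv)))
  # validation = calibration implies RMSEP = RMSEC
  met2 <- evaluate_model(m, Xc, cc, Xc, cc)
  expect_equal(met2$rmsep, met2$rmsec)
  # empty validation set: absent, not zero
  met3 <- evaluate_model(m, Xc, cc)
  expect_true(is.na(met3$rmsep) && is.na(met3$r2_pred))
  expect_identical(met3$n_val, 0L)
})

test_that("full-spectrum models rank the weak analyte worst on the fixture", {
  sim <- simulate_dataset(generator_config(grid = make_grid(800, 2200, 2)),
                          seed = 1)
  r2 <- vapply(licorice_analytes(), function(a) {
    al <- align_dataset(sim$dataset, sim$references, a)
    sp <- ks_split(al$X, 2 / 3)
    Xc <- al$X[sp$calibration_idx, ]; cc <- al$c[sp$calibration_idx]
    cv <- loo_cv(Xc, cc, 8)
    m <- pls_fit(Xc, cc, cv$chosen)
    r_squared(al$c[sp$validation_idx],
              pls_predict(m, al$X[sp$validation_idx, ]))
  }, 0)
  strong <- r2[c("glycyrrhizic_acid", "liquiritin", "total_flavonoids")]
  expect_true(all(strong > 0.98))
  expect_lt(r2["isoliquiritin"], min(strong))
})

test_that("metrics on the small seed-1 fixture match the frozen golden record", {
  # regression fixture established at the first correct build; guards the
  # whole chain simulate -> split -> fit -> evaluate against silent drift
  cfg <- generator_config(grid = make_grid(800, 2200, 5),
                          n_per_phase = c(8, 7, 6))
  sim <- simulate_dataset(cfg, seed = 1)
  al <- align_dataset(sim$dataset, sim$references, "total_flavonoids")
  sp <- ks_split(al$X, 2 / 3)
  Xc <- al$X[sp$calibration_idx, ]; cc <- al$c[sp$calibration_idx]
  Xv <- al$X[sp$validation_idx, ]; cv_ <- al$c[sp$validation_idx]
  met <- evaluate_model(pls_fit(Xc, cc, 5), Xc, cc, Xv, cv_)
  golden <- c(rmsec = 0.00420456259286545, r2_cal = 0.999955819467901,
              rmsecv = 0.0263187529619874, r2_cv = 0.998268908941836,
              rmsep = 0.0172005410591683, r2_pred = 0.998692726370642)
  for (f in names(golden)) {
    expect_equal(met[[f]], unname(golden[f]), tolerance = 1e-10, info = f)
  }
})
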