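test_that("MWPLS localizes a single informative band", {
  g <- make_grid(800, 2200, 5)   # 280 variables
  set.seed(51)
  wl <- grid_wavelengths(g)
  sig <- exp(-(wl - 1500)^2 / (2 * 10^2))
  conc <- runif(30, 0.2, 2)
  X <- outer(conc, sig) + matrix(rnorm(30 * g$n_points, 0, 0.02), 30)
  res <- mwpls_scan(X, conc, g, H_values = c(13, 21), A_max = 3)
  H <- res$best_window$H
  expect_lt(abs(res$best_window$center_nm - 1500), (H / 2) * g$step_nm + 1e-9)
  expect_equal(mwpls_verdict(res)$decision, "informative")
})

test_that("a window spanning the whole grid reproduces the full-spectrum RMSECV", {
  g <- make_grid(1000, 1105, 5)  # 21 variables
  set.seed(52)
  X <- matrix(rnorm(12 * 21), 12)
  y <- rnorm(12)
  res <- mwpls_scan(X, y, g, H_values = 21, A_max = 3)
  expect_equal(res$windows$H21$rmsecv, res$full_spectrum_rmsecv,
               tolerance = 1e-12)
  expect_equal(mwpls_verdict(res)$decision, "inappropriate")  # strict <
})

test_that("pure-noise response yields no informative window", {
  g <- make_grid(800, 2200, 10)  # 140 variables
  set.seed(53)
  X <- matrix(rnorm(25 * g$n_points), 25)
  y <- rnorm(25)                 # unrelated to X
  res <- mwpls_scan(X, y, g, H_values = c(13, 17), A_max = 3)
  # windows may beat the benchmark by CV noise only, never substantially
  expect_gt(res$best_window$rmsecv, 0.75 * res$full_spectrum_rmsecv)
})

test_that("SiPLS search is exhaustive and equals the double-loop oracle", {
  g <- make_grid(1000, 1100, 2)  # 50 variables, 5 intervals of 10
  set.seed(54)
  n <- 14
  X <- matrix(rnorm(n * g$n_points), n)
  y <- 2 * rowMeans(X[, 11:20]) + rnorm(n, 0, 0.1)
  res <- sipls_search(X, y, g, n_intervals = 5, k = 2, A_max = 3)
  expect_equal(nrow(res$ranking), choose(5, 2))

  # independent double loop over combinations and per-fold refits
  combos <- combn(5, 2)
  oracle <- data.frame(combination = character(0), n_factors = integer(0),
                       rmsecv = numeric(0))
  for (j in seq_len(ncol(combos))) {
    cols <- unlist(lapply(combos[, j], function(i) ((i - 1) * 10 + 1):(i * 10)))
    A_cap <- min(3, length(cols) - 1, n - 2)
    lo <- loo_press_r(X[, cols, drop = FALSE], y, A_cap)
    a_best <- which.min(lo$press)
    oracle <- rbind(oracle, data.frame(
      combination = paste(combos[, j], collapse = ","),
      n_factors = a_best, rmsecv = sqrt(lo$press[a_best] / n)))
  }
  oracle <- oracle[order(oracle$rmsecv, oracle$combination), ]
  expect_equal(res$ranking$combination, oracle$combination)
  expect_equal(res$ranking$rmsecv, oracle$rmsecv, tolerance = 1e-8)
  expect_equal(res$ranking$n_factors, oracle$n_factors)
})

test_that("SiPLS recovers the intervals holding all of the signal", {
  g <- make_grid(800, 2200, 5)   # 280 variables, 20 intervals of 14
  dat <- confined_signal_data(g, c(4, 8, 14), 20, n = 40, seed = 55)
  res <- sipls_search(dat$X, dat$c, g, n_intervals = 20, k = 3, A_max = 3)
  expect_identical(res$best$intervals, c(4L, 8L, 14L))
  expect_match(res$best$nm_ranges, "1010-1080, 1290-1360, 1710-1780")
  # nm reporting is single-sourced through subinterval_bounds
  b <- subinterval_bounds(4, 20, g)
  expect_match(res$best$nm_ranges, sprintf("%g-%g", b$lower_nm, b$upper_nm))
})

test_that("n_intervals = k collapses to the full spectrum", {
  g <- make_grid(1000, 1060, 2)
  set.seed(56)
  X <- matrix(rnorm(10 * 30), 10)
  y <- rowSums(X[, 1:5]) + rnorm(10, 0, 0.1)
  res <- sipls_search(X, y, g, n_intervals = 3, k = 3, A_max = 3)
  expect_equal(nrow(res$ranking), 1)
  cv <- loo_cv(X, y, 3)
  expect_equal(res$best$rmsecv, min(cv$rmsecv), tolerance = 1e-10)
  expect_error(sipls_search(X, y, g, n_intervals = 3, k = 4), "k must be")
})

test_that("final masked models behave like their unmasked equivalents", {
  g <- make_grid(800, 2200, 5)
  dat <- confined_signal_data(g, c(4, 8, 14), 20, n = 30, seed = 57,
                              noise_sd = 0.05)
  # full-grid mask is identical to a plain PLS fit
  full <- build_final_model(dat$X, dat$c, g, 1, 2, n_intervals = 1)
  plain <- pls_fit(dat$X, dat$c, 2)
  expect_equal(full$regression_vector, plain$regression_vector)
  # interval model predicts from full-grid spectra via its stored mask
  m <- build_final_model(dat$X, dat$c, g, c(4, 8, 14), 2, n_intervals = 20)
  cols <- subinterval_columns(c(4, 8, 14), 20, g)
  expect_equal(pls_predict(m, dat$X),
               pls_predict(m, dat$X[, cols]))
  # the selection helps: the fixture's noisy high-wavelength region sits
  # outside the informative intervals, so the full-spectrum model carries it
  dat <- confined_signal_data(g, c(4, 8, 14), 20, n = 30, seed = 57,
                              noise_sd = 0.05, noisy_tail_sd = 0.3)
  val <- confined_signal_data(g, c(4, 8, 14), 20, n = 25, seed = 59,
                              noise_sd = 0.05, noisy_tail_sd = 0.3)
  si <- sipls_search(dat$X, dat$c, g, n_intervals = 20, k = 3, A_max = 3)
  msel <- build_final_model(dat$X, dat$c, g, si$best, si$best$n_factors)
  cvfull <- loo_cv(dat$X, dat$c, 3)
  mfull <- pls_fit(dat$X, dat$c, cvfull$chosen)
  expect_lte(rmse(val$c, pls_predict(msel, val$X)),
             rmse(val$c, pls_predict(mfull, val$X)))
  expect_error(build_final_model(dat$X, dat$c, g, integer(0), 2), "empty")
})
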