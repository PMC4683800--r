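test_that("relative_error matches its formula and is scale-invariant", {
  expect_equal(relative_error(2, 2), 0)
  expect_equal(relative_error(2, 1), 50)
  expect_equal(relative_error(1, 1.0182), 1.82)
  set.seed(61)
  r <- runif(10, 0.5, 2); p <- r * runif(10, 0.8, 1.2)
  expect_equal(relative_error(7.3 * r, 7.3 * p), relative_error(r, p))
  expect_error(relative_error(0, 1), "> 0")
})

test_that("phase means reproduce the published first/second-phase averages", {
  pub <- published_phase_errors()
  recompute <- function(phase, analyte) {
    phase_mean(pub$per_sample[pub$per_sample$phase == phase, analyte])
  }
  # phase 1: all four analytes match the printed row at 2 decimals
  for (a in licorice_analytes()) {
    printed <- pub$printed_means[pub$printed_means$phase == 1, a]
    expect_equal(round_half_up(recompute(1, a), 2), printed, info = a)
  }
  # phase 2: three analytes match; the glycyrrhizic acid entry is a known
  # misprint (printed 4.42, column mean 4.43)
  for (a in c("liquiritin", "isoliquiritin", "total_flavonoids")) {
    printed <- pub$printed_means[pub$printed_means$phase == 2, a]
    expect_equal(round_half_up(recompute(2, a), 2), printed, info = a)
  }
  expect_equal(round_half_up(recompute(2, "glycyrrhizic_acid"), 2), 4.43)
  expect_equal(phase_mean(c(NA, 7.5, NA)), 7.5)
  expect_error(phase_mean(c(NA_real_, NA_real_)), "no present")
})

test_that("phase_assessment tabulates errors and exclusions per phase", {
  ids <- paste0("s", 1:6)
  phase <- c(1, 1, 2, 2, 3, 3)
  ref <- c(1, 2, NA, 1, 0.5, 0.2)
  pred <- c(1.1, 1.9, 0.8, 1.05, 0.6, 0.3)
  pa <- phase_assessment("liquiritin", ids, phase, ref, pred)
  expect_identical(pa$excluded, "s3")
  expect_equal(unname(pa$phase_means["phase1"]), mean(c(10, 5)))
  expect_equal(unname(pa$phase_means["phase2"]), 5)
  expect_true(is.na(pa$per_sample$relative_error_pct[3]))
})

test_that("the regression F test matches a hand ANOVA and handles collinearity", {
  x <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  y <- c(0.25, 0.48, 0.95, 1.33, 2.05)
  ft <- f_test(y, x, alpha = 0.01)
  # explicit SSR/SSE decomposition of the simple regression of y on x
  fit <- lm(y ~ x)
  an <- anova(fit)
  expect_equal(ft$f_statistic, an$`F value`[1], tolerance = 1e-10)
  expect_identical(ft$df, c(1L, 3L))
  expect_true(ft$significant == (ft$f_statistic > qf(0.99, 1, 3)))
  # perfect collinearity
  ft2 <- f_test(x, x)
  expect_identical(ft2$f_statistic, Inf)
  expect_true(ft2$significant)
  expect_error(f_test(c(1, 2), c(1, 2)), "at least 3")
})

test_that("F-test type-I error under the null tracks alpha", {
  set.seed(62)
  n <- 93
  ref <- runif(n, 0.1, 2)
  rejections <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    pred <- rnorm(n)             # independent of the reference values
    if (f_test(pred, ref, alpha = 0.01)$significant) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / n_sim - 0.01), 0.02)
})

test_that("critical_f agrees with the incomplete-beta inversion oracle", {
  cases <- list(c(0.05, 1, 10), c(0.01, 1, 91), c(0.10, 3, 40))
  for (cs in cases) {
    expect_equal(critical_f(cs[1], cs[2:3]),
                 critical_f_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-6)
  }
  expect_equal(critical_f(0.05, c(1, 10)), 4.965, tolerance = 1e-3)
  expect_equal(critical_f(0.01, c(1, 91)), 6.92, tolerance = 1e-2)
  # alpha -> 1 limit
  expect_lt(critical_f(0.999, c(2, 30)), 0.01)
  expect_error(critical_f(1.2, c(1, 10)), "alpha")
  expect_error(critical_f(0.05, c(-1, 10)), "df")
})

test_that("the detection limit is positive, noise-monotone and vanishes without noise", {
  # noiseless calibration: MDL ~ 0
  cfg0 <- noiseless_config()
  sim0 <- simulate_dataset(cfg0, seed = 63)
  al0 <- align_dataset(sim0$dataset, sim0$references, "glycyrrhizic_acid")
  m0 <- pls_fit(al0$X, al0$c, 5)
  mdl0 <- mdl_estimate(m0, al0$X, al0$c)
  expect_lt(mdl0$mdl_mg_per_ml, 1e-6)

  # assay noise: MDL > 0 but below the smallest calibration level for the
  # three strong analytes
  sim <- simulate_dataset(small_config(), seed = 64)
  for (a in c("glycyrrhizic_acid", "liquiritin", "total_flavonoids")) {
    al <- align_dataset(sim$dataset, sim$references, a)
    cv <- loo_cv(al$X, al$c, 6)
    m <- pls_fit(al$X, al$c, cv$chosen)
    mdl <- mdl_estimate(m, al$X, al$c)
    expect_gt(mdl$mdl_mg_per_ml, 0)
    expect_lt(mdl$mdl_mg_per_ml, min(al$c[al$c > 0]))
    expect_equal(mdl$mdl_ppm, mdl$mdl_mg_per_ml * 1000)
  }

  # a larger assay error inflates the regression scatter, hence the MDL
  simA <- simulate_dataset(small_config(assay_rel_sd = 0.01), seed = 65)
  simB <- simulate_dataset(small_config(assay_rel_sd = 0.10), seed = 65)
  alA <- align_dataset(simA$dataset, simA$references, "liquiritin")
  alB <- align_dataset(simB$dataset, simB$references, "liquiritin")
  mA <- pls_fit(alA$X, alA$c, 4)
  mB <- pls_fit(alB$X, alB$c, 4)
  expect_gt(mdl_estimate(mB, alB$X, alB$c)$mdl_mg_per_ml,
            mdl_estimate(mA, alA$X, alA$c)$mdl_mg_per_ml)
})
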