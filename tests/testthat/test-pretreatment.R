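test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  x <- seq(0, 10, by = 0.1)
  n <- length(x)
  # smoothing leaves a cubic unchanged (polyorder 3), edges included
  cubic <- 2 + 0.5 * x - 0.3 * x^2 + 0.04 * x^3
  out <- sg_filter(cubic, window = 9, polyorder = 3, deriv = 0)
  expect_equal(out, cubic, tolerance = 1e-10)
  # first derivative of a line is its slope, scaled per nm
  lin <- 1.5 + 2.5 * x
  d1 <- sg_filter(lin, window = 11, polyorder = 2, deriv = 1, step_nm = 0.1)
  expect_equal(d1, rep(2.5, n), tolerance = 1e-10)
  # second derivative of a quadratic equals the analytic 2c everywhere
  quad <- 1 - 0.7 * x + 0.9 * x^2
  d2 <- sg_filter(quad, window = 9, polyorder = 3, deriv = 2, step_nm = 0.1)
  expect_equal(d2, rep(1.8, n), tolerance = 1e-8)
  expect_error(sg_filter(quad, window = 8, polyorder = 2), "odd")
  expect_error(sg_filter(quad, window = 9, polyorder = 9), "polyorder")
})

test_that("SNV standardizes rows and is affine-invariant", {
  set.seed(11)
  X <- matrix(rnorm(5 * 40), 5)
  out <- snv(X)
  expect_lt(max(abs(rowMeans(out))), 1e-10)
  expect_equal(apply(out, 1, sd), rep(1, 5))
  expect_equal(snv(3 * X + 7), out)
  expect_error(snv(rbind(X, 2)), "near-constant")
})

test_that("normalize_rows scales to unit norm and is scale-invariant", {
  set.seed(12)
  X <- matrix(rnorm(4 * 30), 4)
  out <- normalize_rows(X)
  expect_equal(sqrt(rowSums(out^2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(normalize_rows(5 * X), out)
  expect_equal(normalize_rows(out), out)
  expect_error(normalize_rows(rbind(X, 0)), "zero spectrum")
})

test_that("MSC corrects pure gain/offset scatter against the mean spectrum", {
  set.seed(13)
  base <- exp(-((1:80) - 40)^2 / 200) + 0.5
  a <- runif(6, 0.8, 1.2)
  b <- rnorm(6, 0, 0.1)
  X <- outer(a, base) + b
  f <- msc_fit(X)
  # the reference spectrum itself is unchanged
  ref <- f$state$reference
  expect_equal(drop(msc_apply(f, matrix(ref, 1))), ref, tolerance = 1e-10)
  # a pure gain+offset copy of the reference collapses onto it
  expect_equal(drop(msc_apply(f, matrix(2 * ref + 3, 1))), ref,
               tolerance = 1e-10)
  # mean of per-row OLS slopes on scatter-only data is exactly 1
  slopes <- vapply(seq_len(nrow(X)), function(i) {
    stats::coef(stats::lm(X[i, ] ~ ref))[2]  # brute-force per-row OLS
  }, 0)
  expect_equal(mean(slopes), 1, tolerance = 1e-8)
  corrected <- msc_apply(f, X)
  expect_equal(apply(corrected, 1, function(r) cor(r, base)),
               rep(1, 6), tolerance = 1e-10)
})

test_that("OSC removes y-orthogonal structure with exactly orthogonal scores", {
  set.seed(14)
  n <- 30; p <- 120
  X <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  f <- osc_fit(X, y, n_components = 2)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, f$state$x_mean)
  for (a in 1:2) {
    t <- Xc %*% f$state$weights[[a]]
    expect_lt(abs(sum(t * yc)) / sqrt(sum(t^2) * sum(yc^2)), 1e-8)
    Xc <- Xc - tcrossprod(drop(t), f$state$loadings[[a]])
  }
  # unrelated y: removed direction ~ leading principal direction of X
  t1 <- sweep(X, 2, f$state$x_mean) %*% f$state$weights[[1]]
  pc1 <- svd(scale(X, scale = FALSE), nu = 1, nv = 0)$u[, 1]
  expect_gt(abs(cor(drop(t1), pc1)), 0.95)
  # idempotency: applying the fitted correction twice changes nothing
  once <- osc_apply(f, X)
  twice <- osc_apply(f, once)
  expect_equal(twice, once, tolerance = 1e-6)
})

test_that("OSC pre-filtering lets PLS explain a y-orthogonal interferent with fewer factors", {
  set.seed(15)
  n <- 40; p <- 150
  sig <- exp(-((1:p) - 60)^2 / 100)
  interf <- exp(-((1:p) - 100)^2 / 300)
  y <- runif(n, 0.2, 2)
  z <- rnorm(n, 0, 2)          # strong structured variation unrelated to y
  X <- outer(y, sig) + outer(z, interf) + matrix(rnorm(n * p, 0, 0.005), n)
  raw_cv <- loo_cv(X, y, 5)
  f <- osc_fit(X, y, 1)
  osc_cv <- loo_cv(osc_apply(f, X), y, 5)
  expect_lt(osc_cv$chosen, raw_cv$chosen)
})

test_that("wavelet denoising reconstructs smooth signals and shrinks noise", {
  x <- seq(0, 1, length.out = 300)
  clean <- sin(2 * pi * x) + 0.5 * exp(-(x - 0.6)^2 / 0.04)
  out <- wavelet_denoise(clean, "db4")
  expect_equal(out, clean, tolerance = 1e-6)

  set.seed(16)
  noise <- rnorm(512)
  den <- wavelet_denoise(noise, "db4")
  expect_lt(var(den), var(noise))

  # Monte-Carlo: denoising reduces RMSE against the clean signal
  worse <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    noisy <- clean + rnorm(length(clean), 0, 0.01)
    den <- wavelet_denoise(noisy, "db4")
    if (sqrt(mean((den - clean)^2)) >= sqrt(mean((noisy - clean)^2))) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
  expect_error(wavelet_denoise(clean, "db99"), "unknown wavelet")
})

test_that("pipelines compose left-to-right and replay stored state only", {
  set.seed(17)
  X <- matrix(rnorm(8 * 64, mean = 2), 8)
  y <- rnorm(8)
  # [raw] is the identity
  raw <- pipeline_fit(list(pretreatment_spec("raw")), X)
  expect_equal(pipeline_apply(raw, X), X)
  # [sg, snv] equals the stepwise computation
  pipe <- pipeline_fit(list(pretreatment_spec("sg", window = 9),
                            pretreatment_spec("snv")), X)
  expect_equal(pipeline_apply(pipe, X),
               snv(sg_filter(X, 9, 2, 0)))
  # OSC without the response is rejected
  expect_error(pipeline_fit(list(pretreatment_spec("osc")), X), "c_cal")
  # row-wise stages commute with row permutation of new data
  pipe2 <- pipeline_fit(list(pretreatment_spec("msc"),
                             pretreatment_spec("snv")), X)
  Xnew <- matrix(rnorm(5 * 64, mean = 2), 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(pipeline_apply(pipe2, Xnew[perm, ]),
               pipeline_apply(pipe2, Xnew)[perm, ])
})
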