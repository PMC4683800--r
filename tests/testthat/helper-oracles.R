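# Independent reference implementations used as oracles. These deliberately
# re-derive results by the most transparent route available (explicit loops,
# normal equations, brute force) and never call the package's fast paths.

# plain-R NIPALS PLS1 on mean-centered data; returns per-factor pieces and
# cumulative-coefficient list
nipals_r <- function(X, y, A) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xd <- sweep(X, 2, xm)
  yd <- y - ym
  W <- P <- matrix(0, ncol(X), A)
  Q <- numeric(A)
  Tm <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    q <- sum(yd * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - q * t
    W[, a] <- w; P[, a] <- p; Q[a] <- q; Tm[, a] <- t
  }
  B <- lapply(seq_len(A), function(a) {
    Wa <- W[, 1:a, drop = FALSE]
    Pa <- P[, 1:a, drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), Q[1:a]))
  })
  list(x_mean = xm, y_mean = ym, W = W, P = P, Q = Q, scores = Tm, B = B)
}

predict_r <- function(fit, X, a) {
  drop(sweep(as.matrix(X), 2, fit$x_mean) %*% fit$B[[a]] + fit$y_mean)
}

# explicit per-fold leave-one-out PRESS
loo_press_r <- function(X, y, A_max) {
  n <- nrow(X)
  pred <- matrix(0, n, A_max)
  for (i in seq_len(n)) {
    f <- nipals_r(X[-i, , drop = FALSE], y[-i], A_max)
    for (a in seq_len(A_max)) pred[i, a] <- predict_r(f, X[i, , drop = FALSE], a)
  }
  press <- colSums((pred - y)^2)
  list(press = press, predictions = pred)
}

# quadratic-time Kennard-Stone re-implementation (nested loops throughout)
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(1:n, sel)) {
      mind <- Inf
      for (s in sel) mind <- min(mind, D[i, s])
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sort(sel)
}

# upper-tail F quantile by inverting the regularized incomplete beta
critical_f_oracle <- function(alpha, df1, df2) {
  cdf <- function(x) stats::pbeta(df1 * x / (df1 * x + df2), df1 / 2, df2 / 2)
  stats::uniroot(function(x) cdf(x) - (1 - alpha), c(1e-12, 1e6),
                 tol = 1e-12)$root
}

# one-analyte dataset whose signal lives entirely inside a given set of
# subintervals; everything else is noise
confined_signal_data <- function(grid, intervals, n_intervals, n = 40,
                                 seed = 42, noise_sd = 0.01,
                                 noisy_tail_sd = 0) {
  set.seed(seed)
  wl <- grid_wavelengths(grid)
  sig <- numeric(grid$n_points)
  for (i in intervals) {
    b <- subinterval_bounds(i, n_intervals, grid)
    center <- (b$lower_nm + b$upper_nm) / 2
    sig <- sig + exp(-(wl - center)^2 / (2 * 12^2))
  }
  # hard-confine: zero outside the chosen intervals so no signal leaks
  keep <- subinterval_columns(intervals, n_intervals, grid)
  mask <- rep(0, grid$n_points); mask[keep] <- 1
  sig <- sig * mask
  conc <- runif(n, 0.2, 2)
  X <- outer(conc, sig) + matrix(rnorm(n * grid$n_points, 0, noise_sd),
                                 n, grid$n_points)
  if (noisy_tail_sd > 0) {     # mimic the noisy 2000+ nm combination region
    hi <- wl >= 2000
    X[, hi] <- X[, hi] + matrix(rnorm(n * sum(hi), 0, noisy_tail_sd), n)
  }
  list(X = X, c = conc, signal = sig)
}

# small simulated extraction run shared across tests
small_config <- function(...) {
  generator_config(grid = make_grid(800, 2200, 5), n_per_phase = c(8, 7, 6),
                   ...)
}

noiseless_config <- function(grid = make_grid(800, 2200, 5),
                             n_per_phase = c(8, 7, 6)) {
  kin <- default_kinetic_specs()
  for (a in names(kin)) kin[[a]]$t_lag <- 0  # keep all concentrations > 0
  generator_config(grid = grid, n_per_phase = n_per_phase, kinetics = kin,
                   gain_sd = 0, offset_sd = 0, noise_sd = 0,
                   noise_extra_sd = 0, baseline = c(0, 0), assay_rel_sd = 0,
                   assay_abs_sd = 0)
}
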