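#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with one response: `X` and `c` are
#' mean-centered (no variance scaling -- absorbance units are commensurate)
#' and score/loading pairs are extracted by deflation. The returned model
#' carries the regression vector in the wavelength domain, so prediction is
#' affine in the spectrum: `c_hat = (x - x_mean) . b + c_mean`.
#'
#' @param X Calibration spectra (samples x variables).
#' @param c Calibration concentrations (mg/mL).
#' @param n_factors Number of latent factors; must be
#'   `<= min(n_samples - 1, n_variables)`.
#' @param variable_mask Optional 1-based column indices of `X`'s parent grid
#'   recorded on the model (for interval-restricted models). Defaults to all
#'   columns of `X`.
#' @param n_full Number of columns of the parent (full-grid) spectra the
#'   `variable_mask` indexes into; lets [pls_predict()] accept full-grid
#'   spectra for a masked model. Defaults to `ncol(X)`.
#' @return Object of class `pls_model`: `n_factors`, `x_mean`, `y_mean`,
#'   `weights`, `x_loadings`, `y_loadings`, `regression_vector`, `scores`,
#'   `variable_mask`.
#' @export
pls_fit <- function(X, c, n_factors, variable_mask = NULL, n_full = NULL) {
  X <- as.matrix(X)
  c <- as.numeric(c)
  n <- nrow(X)
  if (length(c) != n) stop("c length must match rows of X")
  if (stats::var(c) <= 0) stop("response has zero variance")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors > min(n - 1, ncol(X))) {
    stop(sprintf("n_factors = %d exceeds min(n_samples - 1, n_variables) = %d",
                 n_factors, min(n - 1, ncol(X))))
  }
  if (is.null(variable_mask)) variable_mask <- seq_len(ncol(X))
  if (length(variable_mask) != ncol(X)) {
    stop("variable_mask length must equal ncol(X)")
  }
  if (is.null(n_full)) n_full <- ncol(X)
  if (max(variable_mask) > n_full) stop("variable_mask exceeds n_full")
  f <- cpp_pls_fit(X, c, as.integer(n_factors))
  structure(
    list(n_factors = as.integer(n_factors),
         n_factors_used = f$n_factors_used,
         x_mean = as.vector(f$x_mean), y_mean = f$y_mean,
         weights = f$weights, x_loadings = f$x_loadings,
         y_loadings = as.vector(f$y_loadings),
         regression_vector = as.vector(f$coefficients[, n_factors]),
         coefficients_by_factor = f$coefficients,
         scores = f$scores,
         variable_mask = as.integer(variable_mask),
         n_full = as.integer(n_full),
         n_cal = n),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent factors, %d variables, fit on %d samples\n",
              x$n_factors, length(x$regression_vector), x$n_cal))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' @param model A `pls_model`.
#' @param X Spectra whose columns match the model's variables (either
#'   already masked, or full-grid spectra from which `variable_mask` columns
#'   are taken).
#' @return Numeric vector of predicted concentrations.
#' @export
pls_predict <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  p <- length(model$regression_vector)
  if (ncol(X) != p) {
    if (ncol(X) == model$n_full) {
      X <- X[, model$variable_mask, drop = FALSE]
    } else {
      stop(sprintf("X has %d columns; model expects %d (or %d full-grid)",
                   ncol(X), p, model$n_full))
    }
  }
  as.vector(sweep(X, 2, model$x_mean) %*% model$regression_vector +
              model$y_mean)
}

#' Root-mean-square error
#'
#' `sqrt(sum((c_i - c_hat_i)^2) / I)` over the `I` samples of a set; the
#' common scale for RMSEC (calibration), RMSECV (cross-validation) and
#' RMSEP (prediction).
#'
#' @param c Reference concentrations.
#' @param c_hat Predicted concentrations.
#' @return RMSE in the units of `c`.
#' @export
rmse <- function(c, c_hat) {
  if (length(c) == 0) stop("empty input")
  if (length(c) != length(c_hat)) stop("length mismatch")
  sqrt(sum((c - c_hat)^2) / length(c))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` against the mean of the reference values (not a squared
#' correlation; vendor software differs on this point).
#'
#' @inheritParams rmse
#' @return R-squared (<= 1; can be negative for a bad model).
#' @export
r_squared <- function(c, c_hat) {
  if (length(c) != length(c_hat)) stop("length mismatch")
  sst <- sum((c - mean(c))^2)
  if (sst <= 0) stop("reference values are constant")
  1 - sum((c - c_hat)^2) / sst
}

#' Leave-one-out cross-validation and PRESS-based factor selection
#'
#' For each held-out sample the model is refit on the remaining samples
#' (centering recomputed per fold) and the sample predicted with 1..`A_max`
#' factors. `PRESS(A)` is the sum of squared LOO residuals and
#' `RMSECV(A) = sqrt(PRESS(A)/n)`. The chosen factor count minimizes PRESS;
#' ties -- including numerical ties within a relative 1e-8, as arise when
#' extra factors no longer change the model -- go to the smaller count
#' (parsimony).
#'
#' @param X Spectra matrix.
#' @param c Concentrations.
#' @param A_max Maximum factor count; must be `<= n - 2`.
#' @return Object of class `press_curve`: `factors`, `press`, `rmsecv`,
#'   `chosen`, and the `n x A_max` matrix of LOO `predictions`.
#' @export
loo_cv <- function(X, c, A_max) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (A_max > n - 2) {
    stop(sprintf("A_max = %d exceeds n - 2 = %d", A_max, n - 2))
  }
  if (A_max < 1) stop("A_max must be >= 1")
  A_max <- min(A_max, ncol(X))
  y <- as.numeric(c)
  lo <- cpp_loo_press(X, y, as.integer(A_max))
  press <- as.vector(lo$press)
  # smallest factor count whose PRESS ties the minimum; the tie band has a
  # relative part (extra factors changing nothing) and an absolute floor at
  # 1e-10 of the response sum of squares (a fit this exact is exact)
  tie <- min(press) * (1 + 1e-8) + 1e-10 * sum((y - mean(y))^2)
  chosen <- which(press <= tie)[1]
  structure(
    list(factors = seq_len(A_max), press = press,
         rmsecv = sqrt(press / n),
         chosen = chosen,
         predictions = lo$predictions),
    class = "press_curve"
  )
}

#' @export
print.press_curve <- function(x, ...) {
  cat(sprintf("<press_curve> A = 1..%d, chosen %d (PRESS = %.6g)\n",
              max(x$factors), x$chosen, x$press[x$chosen]))
  invisible(x)
}

#' Model metrics on calibration and validation sets
#'
#' Computes the standard chemometric indicator suite for a fitted model:
#' RMSEC and calibration R2 from the training residuals, RMSECV and
#' cross-validated R2 from leave-one-out refits at the model's factor
#' count, RMSEP and prediction R2 from the independent validation set.
#' With an empty validation set the prediction entries are `NA` (absent),
#' never zero.
#'
#' @param model A `pls_model` fitted on `(X_cal, c_cal)`.
#' @param X_cal,c_cal Calibration data (columns already masked to the
#'   model's variables).
#' @param X_val,c_val Validation data; may be `NULL`/empty.
#' @return Object of class `model_metrics` with fields `rmsec`, `r2_cal`,
#'   `rmsecv`, `r2_cv`, `rmsep`, `r2_pred`, `n_factors`, `n_cal`, `n_val`.
#' @export
evaluate_model <- function(model, X_cal, c_cal, X_val = NULL, c_val = NULL) {
  stopifnot(inherits(model, "pls_model"))
  c_hat_cal <- pls_predict(model, X_cal)
  cv <- loo_cv(X_cal, c_cal, model$n_factors)
  cv_pred <- cv$predictions[, model$n_factors]
  has_val <- !is.null(X_val) && NROW(X_val) > 0
  structure(
    list(rmsec = rmse(c_cal, c_hat_cal),
         r2_cal = r_squared(c_cal, c_hat_cal),
         rmsecv = cv$rmsecv[model$n_factors],
         r2_cv = r_squared(c_cal, cv_pred),
         rmsep = if (has_val) rmse(c_val, pls_predict(model, X_val)) else NA_real_,
         r2_pred = if (has_val) r_squared(c_val, pls_predict(model, X_val)) else NA_real_,
         n_factors = model$n_factors,
         n_cal = length(c_cal),
         n_val = if (has_val) length(c_val) else 0L),
    class = "model_metrics"
  )
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf(
    "<model_metrics> A=%d | RMSEC %.4f (R2 %.4f) | RMSECV %.4f (R2 %.4f) | RMSEP %s (R2 %s)\n",
    x$n_factors, x$rmsec, x$r2_cal, x$rmsecv, x$r2_cv,
    ifelse(is.na(x$rmsep), "NA", sprintf("%.4f", x$rmsep)),
    ifelse(is.na(x$r2_pred), "NA", sprintf("%.4f", x$r2_pred))
  ))
  invisible(x)
}
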