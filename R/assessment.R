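#' Relative prediction error
#'
#' `|predicted - reference| / reference * 100`, the phase-wise assessment
#' statistic. Scale-invariant: multiplying both inputs by a positive
#' constant leaves it unchanged.
#'
#' @param reference Reference concentration(s), > 0.
#' @param predicted Predicted concentration(s).
#' @return Relative error(s) in percent.
#' @export
relative_error <- function(reference, predicted) {
  if (any(reference <= 0, na.rm = TRUE)) {
    stop("relative error requires reference > 0")
  }
  abs(predicted - reference) / reference * 100
}

#' Mean relative error over the present values of a phase
#'
#' Missing entries ("NA samples" -- samples without a reference value for
#' the analyte, hence never entering the model) are excluded from the mean.
#' Full precision is kept internally; use `round_half_up(x, 2)` for the
#' 2-decimal display convention.
#'
#' @param errors Numeric vector of relative errors (percent), `NA` allowed.
#' @return Arithmetic mean of the present values.
#' @export
phase_mean <- function(errors) {
  present <- errors[!is.na(errors)]
  if (length(present) == 0) stop("no present relative errors in this phase")
  mean(present)
}

#' Round half away from zero at a given number of decimals
#'
#' Display convention for phase-mean tables (base R `round` rounds half to
#' even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Phase-wise assessment of a calibration model
#'
#' Tabulates, per validation sample, the reference value, prediction and
#' relative error, and summarizes the mean relative error per extraction
#' phase.
#'
#' @param analyte Analyte name.
#' @param ids Sample identifiers.
#' @param phase Extraction phase per sample (1/2/3).
#' @param reference Reference concentrations (mg/mL), `NA` where the assay
#'   is missing. Samples with a zero (or negative) reference are excluded
#'   like missing ones: a relative error is undefined there.
#' @param predicted Predicted concentrations (mg/mL).
#' @return Object of class `phase_assessment`: `per_sample` data.frame,
#'   `phase_means` named vector (percent), `excluded` ids.
#' @export
phase_assessment <- function(analyte, ids, phase, reference, predicted) {
  stopifnot(length(ids) == length(phase), length(phase) == length(reference),
            length(reference) == length(predicted))
  ok <- !is.na(reference) & reference > 0
  rel <- rep(NA_real_, length(ids))
  rel[ok] <- relative_error(reference[ok], predicted[ok])
  per_sample <- data.frame(
    sample_id = ids, phase = as.integer(phase),
    reference_mg_per_ml = reference, predicted_mg_per_ml = predicted,
    relative_error_pct = rel, stringsAsFactors = FALSE
  )
  means <- vapply(1:3, function(p) {
    e <- rel[per_sample$phase == p]
    if (all(is.na(e))) NA_real_ else phase_mean(e)
  }, 0)
  structure(
    list(analyte = analyte, per_sample = per_sample,
         phase_means = stats::setNames(means, paste0("phase", 1:3)),
         excluded = ids[!ok]),
    class = "phase_assessment"
  )
}

#' @export
print.phase_assessment <- function(x, ...) {
  cat(sprintf("<phase_assessment> %s: mean relative error %s %%\n",
              x$analyte,
              paste(sprintf("%s=%.2f", names(x$phase_means),
                            round_half_up(x$phase_means, 2)),
                    collapse = ", ")))
  invisible(x)
}

#' Regression F test of predictions against the reference method
#'
#' Tests the linear relationship between NIR predictions and reference
#' values via the F statistic of the simple linear regression of predicted
#' on reference: `F = SSR / (SSE / (n - 2))` with degrees of freedom
#' `(1, n - 2)`. A significant F (above the upper-tail critical value at
#' `alpha`) indicates the two methods agree beyond chance.
#'
#' @param predicted NIR-predicted concentrations.
#' @param reference Reference-assay concentrations.
#' @param alpha Significance level (default 0.01).
#' @return Object of class `f_test_result`: `f_statistic`, `df`,
#'   `critical_value`, `alpha`, `significant`. Perfect collinearity gives
#'   `f_statistic = Inf`, significant.
#' @export
f_test <- function(predicted, reference, alpha = 0.01) {
  n <- length(reference)
  if (n < 3) stop("F test needs at least 3 samples")
  if (length(predicted) != n) stop("length mismatch")
  if (stats::var(reference) <= 0) stop("reference values are constant")
  xc <- reference - mean(reference)
  yc <- predicted - mean(predicted)
  sxx <- sum(xc^2)
  sxy <- sum(xc * yc)
  ssr <- sxy^2 / sxx
  sse <- sum(yc^2) - ssr
  f <- if (sse <= .Machine$double.eps * sum(yc^2)) Inf else
    ssr / (sse / (n - 2))
  crit <- critical_f(alpha, c(1, n - 2))
  structure(
    list(f_statistic = f, df = c(1L, n - 2L), critical_value = crit,
         alpha = alpha, significant = f > crit),
    class = "f_test_result"
  )
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("<f_test_result> F(%d, %d) = %.4g vs critical %.4g at alpha = %g: %s\n",
              x$df[1], x$df[2], x$f_statistic, x$critical_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Upper-tail critical value of the F distribution
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df Length-2 positive degrees of freedom `(numerator, denominator)`.
#' @return The value `F*` with `P(F > F*) = alpha`.
#' @export
critical_f <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(df) != 2 || any(df <= 0)) stop("df must be two positive values")
  stats::qf(1 - alpha, df[1], df[2])
}

#' Multivariate detection limit (pseudounivariate variant)
#'
#' Estimates the smallest concentration the calibration can reliably
#' distinguish from zero. The multivariate model is collapsed to its
#' pseudounivariate calibration line by regressing the fitted predictions
#' on the reference concentrations over the calibration set;
#' `MDL = Delta(alpha, beta) * s0 / slope`, where `s0` is the standard
#' error of the estimated response at zero concentration
#' (`s * sqrt(1/n + xbar^2/Sxx)`) and
#' `Delta(0.05, 0.05) = z_{0.95} + z_{0.95} ~= 3.30` accounts for both false
#' positive and false negative rates.
#'
#' The ppm figure assumes extract density 1 g/mL, i.e. 1 mg/mL = 1000 ppm.
#'
#' @param model A fitted `pls_model`.
#' @param X_cal Calibration spectra (masked as the model expects).
#' @param c_cal Calibration concentrations (mg/mL).
#' @param alpha,beta False positive / false negative rates (default 0.05).
#' @return Object of class `mdl_result`: `mdl_mg_per_ml`, `mdl_ppm`,
#'   `method`, `inputs` (slope, s0, delta, n).
#' @export
mdl_estimate <- function(model, X_cal, c_cal, alpha = 0.05, beta = 0.05) {
  stopifnot(inherits(model, "pls_model"))
  c_hat <- pls_predict(model, X_cal)
  n <- length(c_cal)
  xc <- c_cal - mean(c_cal)
  sxx <- sum(xc^2)
  slope <- sum(xc * (c_hat - mean(c_hat))) / sxx
  if (slope <= 0) stop("pseudounivariate slope must be > 0")
  resid <- c_hat - (mean(c_hat) + slope * xc)
  s <- sqrt(sum(resid^2) / (n - 2))
  s0 <- s * sqrt(1 / n + mean(c_cal)^2 / sxx)
  delta <- stats::qnorm(1 - alpha) + stats::qnorm(1 - beta)
  mdl <- delta * s0 / slope
  structure(
    list(mdl_mg_per_ml = mdl, mdl_ppm = mdl * 1000,
         method = "pseudounivariate calibration line",
         inputs = list(slope = slope, s0 = s0, delta = delta, n = n,
                       alpha = alpha, beta = beta)),
    class = "mdl_result"
  )
}

#' @export
print.mdl_result <- function(x, ...) {
  cat(sprintf("<mdl_result> MDL = %.4g mg/mL (%.3g ppm at density 1 g/mL), %s\n",
              x$mdl_mg_per_ml, x$mdl_ppm, x$method))
  invisible(x)
}

#' Assemble the structured end-of-run report
#'
#' Collects, per analyte, the pretreatment comparison table, the selected
#' pretreatment, the moving-window verdict, the interval-selection ranking
#' head, the final model metrics, the phase assessment, the F test and the
#' detection limit, into one machine-readable list with a human-readable
#' print method. [write_report()] persists it as delimited tables plus a
#' JSON summary; regenerating from the same artifacts is byte-identical.
#'
#' @param analyte_results Named list (per analyte) as produced by
#'   [run_workflow()].
#' @param config The run configuration used.
#' @return Object of class `workflow_report`.
#' @export
build_report <- function(analyte_results, config) {
  structure(list(analytes = analyte_results, config = config),
            class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("== NIR extraction workflow report ==\n")
  for (a in names(x$analytes)) {
    r <- x$analytes[[a]]
    cat(sprintf("\n-- %s --\n", a))
    cat(sprintf("  pretreatment: %s | MWPLS: %s | SiPLS best: {%s} (A=%d)\n",
                r$pretreatment_label, r$mwpls$decision,
                paste(r$sipls$best$intervals, collapse = ","),
                r$sipls$best$n_factors))
    m <- r$final_metrics
    cat(sprintf("  RMSEC %.4f | RMSECV %.4f | RMSEP %.4f | R2pred %.4f\n",
                m$rmsec, m$rmsecv, m$rmsep, m$r2_pred))
    cat(sprintf("  phase mean rel. error (%%): %s\n",
                paste(sprintf("%.2f", round_half_up(
                  r$assessment$phase_means, 2)), collapse = " / ")))
    cat(sprintf("  F = %.4g (critical %.3g) | MDL = %.3g ppm\n",
                r$f_test$f_statistic, r$f_test$critical_value,
                r$mdl$mdl_ppm))
  }
  invisible(x)
}

#' @rdname build_report
#' @param report A `workflow_report`.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "workflow_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- list()
  for (a in names(report$analytes)) {
    r <- report$analytes[[a]]
    data.table::fwrite(r$pretreatment_table,
                       file.path(dir, paste0(a, "_pretreatments.csv")))
    data.table::fwrite(utils::head(r$sipls$ranking, 50),
                       file.path(dir, paste0(a, "_sipls_ranking.csv")))
    data.table::fwrite(r$assessment$per_sample,
                       file.path(dir, paste0(a, "_phase_table.csv")))
    m <- r$final_metrics
    summary[[a]] <- list(
      pretreatment = r$pretreatment_label,
      mwpls_decision = r$mwpls$decision,
      sipls_intervals = r$sipls$best$intervals,
      sipls_nm = r$sipls$best$nm_ranges,
      n_factors = m$n_factors,
      rmsec = m$rmsec, rmsecv = m$rmsecv, rmsep = m$rmsep,
      r2_cal = m$r2_cal, r2_cv = m$r2_cv, r2_pred = m$r2_pred,
      phase_mean_relative_error_pct =
        as.list(round_half_up(r$assessment$phase_means, 2)),
      f_statistic = r$f_test$f_statistic,
      f_critical = r$f_test$critical_value,
      mdl_ppm = r$mdl$mdl_ppm
    )
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
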