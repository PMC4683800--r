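#' Default pretreatment ladder
#'
#' The candidate pretreatments compared by the workflow, in ladder order
#' (simpler first; ties in the selection rule fall back to this order):
#' raw, SG(9), SG(11), SG(11)+1D, SG(11)+2D, SNV, MSC, OSC(1), WDS,
#' normalize.
#'
#' @return List of `pretreatment_spec`.
#' @export
default_ladder <- function() {
  list(
    pretreatment_spec("raw"),
    pretreatment_spec("sg", window = 9),
    pretreatment_spec("sg", window = 11),
    pretreatment_spec("sg1d", window = 11),
    pretreatment_spec("sg2d", window = 11),
    pretreatment_spec("snv"),
    pretreatment_spec("msc"),
    pretreatment_spec("osc", n_components = 1),
    pretreatment_spec("wds"),
    pretreatment_spec("normalize")
  )
}

#' Run configuration for the full workflow
#'
#' @param analytes Analytes to model (default all four).
#' @param split_fraction Calibration fraction for the Kennard-Stone split
#'   (default 2/3: 93 samples give 62 calibration / 31 validation).
#' @param ladder Pretreatment candidates (list of `pretreatment_spec`).
#' @param A_max Maximum latent factors everywhere (default 10).
#' @param H_values Moving-window sizes (odd; default `seq(13, 41, 2)`).
#' @param n_intervals,k Interval-selection geometry (default 3-of-20).
#' @param alpha Significance level of the assessment F test (default 0.01).
#' @param rmsep_guard Veto factor of the pretreatment selection rule: a
#'   candidate whose RMSEP exceeds `rmsep_guard` times the best candidate
#'   RMSEP is vetoed regardless of its RMSECV (default 2).
#' @param thin_factor Grid-thinning factor applied before the MWPLS and
#'   SiPLS searches (block averaging; 1 = full grid).
#' @param generator A `generator_config` used when simulating input.
#' @param seed RNG seed for simulation.
#' @return List of class `run_config`.
#' @export
run_config <- function(analytes = licorice_analytes(),
                       split_fraction = 2 / 3,
                       ladder = default_ladder(),
                       A_max = 10,
                       H_values = seq(13, 41, by = 2),
                       n_intervals = 20, k = 3,
                       alpha = 0.01,
                       rmsep_guard = 2,
                       thin_factor = 4,
                       generator = generator_config(),
                       seed = 1L) {
  analytes <- match.arg(analytes, licorice_analytes(), several.ok = TRUE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)")
  }
  if (k > n_intervals) stop("k must be <= n_intervals")
  if (A_max < 1) stop("A_max must be >= 1")
  structure(
    list(analytes = analytes, split_fraction = split_fraction,
         ladder = ladder, A_max = A_max, H_values = H_values,
         n_intervals = n_intervals, k = k, alpha = alpha,
         rmsep_guard = rmsep_guard, thin_factor = thin_factor,
         generator = generator, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Select the working pretreatment from a comparison table
#'
#' Rank candidates by RMSECV, but first veto any candidate whose RMSEP
#' exceeds the best candidate RMSEP by more than `guard` times: a
#' pretreatment that wins cross-validation while collapsing on the
#' independent validation set (the classic over-fitting signature of
#' aggressive response-orthogonal filtering) must not be chosen. Among the
#' survivors the lowest RMSECV wins; exact ties go to the earlier ladder
#' entry.
#'
#' @param metrics_list List of `model_metrics`, one per ladder candidate
#'   (ladder order).
#' @param guard Veto factor (default 2).
#' @return Index of the chosen candidate in `metrics_list`.
#' @export
select_pretreatment <- function(metrics_list, guard = 2) {
  if (length(metrics_list) == 0) stop("no pretreatment candidates")
  rmsep <- vapply(metrics_list, function(m) m$rmsep, 0)
  rmsecv <- vapply(metrics_list, function(m) m$rmsecv, 0)
  if (all(is.na(rmsep))) {
    survivors <- seq_along(metrics_list)
  } else {
    best_rmsep <- min(rmsep, na.rm = TRUE)
    survivors <- which(!is.na(rmsep) & rmsep <= guard * best_rmsep)
    if (length(survivors) == 0) survivors <- seq_along(metrics_list)
  }
  survivors[which.min(rmsecv[survivors])]  # which.min: first (= ladder order)
}

#' Run the full chemometric workflow
#'
#' Per analyte: pair spectra with present reference values, Kennard-Stone
#' split, fit and evaluate every ladder pretreatment (factor count by
#' lowest PRESS), select the working pretreatment by the veto-then-rank
#' rule, scan moving windows and record the verdict against the
#' full-spectrum benchmark, run the exhaustive interval-combination search,
#' fit the final interval-restricted model, and assess it phase-wise
#' (relative errors, F test, detection limit).
#'
#' @param config A `run_config`.
#' @param data Optional list with `dataset` and `references` (as from
#'   [simulate_dataset()]); when `NULL` a dataset is simulated from
#'   `config$generator` and `config$seed`.
#' @param verbose Print stage progress.
#' @return A `workflow_report` (see [build_report()]).
#' @export
run_workflow <- function(config = run_config(), data = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) {
    data <- simulate_dataset(config$generator, seed = config$seed)
  }
  dataset <- data$dataset
  refs <- data$references
  say <- function(...) if (verbose) message(sprintf(...))
  results <- list()
  for (analyte in config$analytes) {
    say("[%s] aligning and splitting", analyte)
    al <- align_dataset(dataset, refs, analyte)
    split <- ks_split(al$X, config$split_fraction, ids = al$ids)
    ic <- split$calibration_idx
    iv <- split$validation_idx
    A_cap <- min(config$A_max, length(ic) - 2)

    say("[%s] comparing %d pretreatments", analyte, length(config$ladder))
    metrics_list <- vector("list", length(config$ladder))
    fits <- vector("list", length(config$ladder))
    for (j in seq_along(config$ladder)) {
      sp <- config$ladder[[j]]
      pipe <- pipeline_fit(list(sp), al$X[ic, , drop = FALSE],
                           c_cal = al$c[ic], step_nm = dataset$grid$step_nm)
      Xc <- pipeline_apply(pipe, al$X[ic, , drop = FALSE])
      Xv <- pipeline_apply(pipe, al$X[iv, , drop = FALSE])
      cv <- loo_cv(Xc, al$c[ic], A_cap)
      model <- pls_fit(Xc, al$c[ic], cv$chosen)
      metrics_list[[j]] <- evaluate_model(model, Xc, al$c[ic], Xv, al$c[iv])
      fits[[j]] <- list(pipe = pipe, model = model)
    }
    chosen_j <- select_pretreatment(metrics_list, config$rmsep_guard)
    chosen_spec <- config$ladder[[chosen_j]]
    say("[%s] selected pretreatment: %s", analyte,
        pretreatment_label(chosen_spec))

    pipe <- fits[[chosen_j]]$pipe
    Xc_full <- pipeline_apply(pipe, al$X[ic, , drop = FALSE])
    Xv_full <- pipeline_apply(pipe, al$X[iv, , drop = FALSE])

    # variable selection on the (optionally thinned) pretreated spectra
    th_c <- thin_grid(Xc_full, dataset$grid, config$thin_factor)
    th_v <- thin_grid(Xv_full, dataset$grid, config$thin_factor)
    H_use <- config$H_values[config$H_values <= th_c$grid$n_points]
    say("[%s] MWPLS scan (%d window sizes)", analyte, length(H_use))
    mw <- mwpls_scan(th_c$X, al$c[ic], th_c$grid, H_values = H_use,
                     A_max = A_cap)
    verdict <- mwpls_verdict(mw)
    say("[%s] MWPLS verdict: %s", analyte, verdict$decision)

    say("[%s] SiPLS %d-of-%d search", analyte, config$k, config$n_intervals)
    si <- sipls_search(th_c$X, al$c[ic], th_c$grid,
                       n_intervals = config$n_intervals, k = config$k,
                       A_max = A_cap)
    final <- build_final_model(th_c$X, al$c[ic], th_c$grid, si$best,
                               si$best$n_factors,
                               n_intervals = config$n_intervals)
    fm <- evaluate_model(final,
                         th_c$X[, final$variable_mask, drop = FALSE],
                         al$c[ic],
                         th_v$X[, final$variable_mask, drop = FALSE],
                         al$c[iv])

    pred_val <- pls_predict(final, th_v$X)
    assess <- phase_assessment(analyte, al$ids[iv], al$phase[iv],
                               al$c[iv], pred_val)
    ft <- f_test(pred_val, al$c[iv], alpha = config$alpha)
    mdl <- mdl_estimate(final, th_c$X[, final$variable_mask, drop = FALSE],
                        al$c[ic])

    results[[analyte]] <- list(
      split = split,
      pretreatment_table = data.frame(
        pretreatment = vapply(config$ladder, pretreatment_label, ""),
        n_factors = vapply(metrics_list, function(m) m$n_factors, 0L),
        rmsec = vapply(metrics_list, function(m) m$rmsec, 0),
        r2_cal = vapply(metrics_list, function(m) m$r2_cal, 0),
        rmsecv = vapply(metrics_list, function(m) m$rmsecv, 0),
        r2_cv = vapply(metrics_list, function(m) m$r2_cv, 0),
        rmsep = vapply(metrics_list, function(m) m$rmsep, 0),
        r2_pred = vapply(metrics_list, function(m) m$r2_pred, 0)
      ),
      pretreatment_label = pretreatment_label(chosen_spec),
      pretreatment_index = chosen_j,
      full_spectrum_metrics = metrics_list[[chosen_j]],
      mwpls = verdict,
      sipls = si,
      final_model = final,
      final_metrics = fm,
      assessment = assess,
      f_test = ft,
      mdl = mdl
    )
  }
  build_report(results, config)
}
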