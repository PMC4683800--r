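#' Moving-window PLS scan
#'
#' Slides a contiguous window of `H` variables across the spectrum (step of
#' one variable) and, at each position, selects the PRESS-optimal factor
#' count by leave-one-out cross-validation and records the window RMSECV.
#' Windows with an RMSECV below the full-spectrum benchmark localize
#' informative wavelength regions; if no window beats the benchmark the
#' moving-window approach is inappropriate for that analyte (see
#' [mwpls_verdict()]).
#'
#' @param X Calibration spectra.
#' @param c Calibration concentrations.
#' @param grid The `wavelength_grid` of `X` (for nm reporting).
#' @param H_values Odd window sizes to scan; default `seq(13, 41, 2)`.
#' @param A_max Maximum latent factors per window model.
#' @param step Window step in variables (default 1).
#' @return Object of class `window_scan_result`: per-H tables of window
#'   centers (nm), chosen factors and RMSECV; `best_window` (H, center nm,
#'   first/last variable, factors, rmsecv); `full_spectrum_rmsecv` and the
#'   factor count it used.
#' @export
mwpls_scan <- function(X, c, grid, H_values = seq(13, 41, by = 2),
                       A_max = 10, step = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(inherits(grid, "wavelength_grid"), grid$n_points == p)
  if (any(H_values > p)) stop("window size H exceeds the variable count")
  if (any(H_values %% 2 == 0)) stop("window sizes H must be odd")
  wl <- grid_wavelengths(grid)

  bench_cv <- loo_cv(X, c, min(A_max, nrow(X) - 2, p))
  benchmark <- bench_cv$rmsecv[bench_cv$chosen]

  per_H <- vector("list", length(H_values))
  names(per_H) <- paste0("H", H_values)
  best <- list(rmsecv = Inf)
  for (hi in seq_along(H_values)) {
    H <- H_values[hi]
    starts <- seq.int(1L, p - H + 1L, by = step)
    subsets <- lapply(starts, function(s) seq.int(s, s + H - 1L))
    res <- cpp_subset_rmsecv(X, as.numeric(c), subsets,
                             as.integer(min(A_max, nrow(X) - 2)))
    centers <- wl[starts + (H - 1L) %/% 2L]
    tab <- data.frame(start = starts, center_nm = centers,
                      n_factors = res$n_factors, rmsecv = res$rmsecv)
    per_H[[hi]] <- tab
    i_min <- which.min(tab$rmsecv)
    if (tab$rmsecv[i_min] < best$rmsecv) {
      best <- list(H = H, start = starts[i_min],
                   center_nm = centers[i_min],
                   first_nm = wl[starts[i_min]],
                   last_nm = wl[starts[i_min] + H - 1L],
                   n_factors = tab$n_factors[i_min],
                   rmsecv = tab$rmsecv[i_min])
    }
  }
  structure(
    list(H_values = H_values, windows = per_H, best_window = best,
         full_spectrum_rmsecv = benchmark,
         full_spectrum_factors = bench_cv$chosen),
    class = "window_scan_result"
  )
}

#' Accept or reject the moving-window selection
#'
#' Mirrors the decision rule of the workflow: a window set is informative
#' only if its best RMSECV is strictly lower than the full-spectrum PLS
#' benchmark; otherwise moving-window selection is declared inappropriate
#' for the analyte.
#'
#' @param result A `window_scan_result`.
#' @param benchmark Full-spectrum RMSECV; defaults to the one stored in
#'   `result`.
#' @return List with `decision` (`"informative"` or `"inappropriate"`),
#'   `best_window` and `benchmark`.
#' @export
mwpls_verdict <- function(result, benchmark = result$full_spectrum_rmsecv) {
  stopifnot(inherits(result, "window_scan_result"))
  if (result$best_window$rmsecv < benchmark) {
    list(decision = "informative", best_window = result$best_window,
         benchmark = benchmark)
  } else {
    list(decision = "inappropriate", best_window = result$best_window,
         benchmark = benchmark)
  }
}

#' Synergy interval PLS exhaustive search
#'
#' Splits the grid into `n_intervals` equidistant subintervals and
#' evaluates every combination of `k` of them (all `choose(n_intervals, k)`
#' joint models): the combination's columns are concatenated, the factor
#' count is chosen by lowest PRESS under leave-one-out cross-validation
#' (capped at `min(A_max, n_variables_in_combination - 1, n - 2)`), and the
#' combination RMSECV recorded. The ranking is sorted by ascending RMSECV
#' with ties going to the lexicographically smaller index set.
#'
#' @param X Calibration spectra.
#' @param c Calibration concentrations.
#' @param grid The `wavelength_grid` of `X`.
#' @param n_intervals Number of equidistant subintervals (default 20).
#' @param k Intervals per combination (default 3).
#' @param A_max Maximum latent factors.
#' @return Object of class `interval_combination_result`: `ranking` (a
#'   data.frame with interval indices, nm ranges, factors, RMSECV, sorted)
#'   and `best` (first row, as a list with an `intervals` integer vector).
#' @export
sipls_search <- function(X, c, grid, n_intervals = 20, k = 3, A_max = 10) {
  X <- as.matrix(X)
  stopifnot(inherits(grid, "wavelength_grid"), grid$n_points == ncol(X))
  n_intervals <- as.integer(n_intervals)
  k <- as.integer(k)
  if (k > n_intervals) stop("k must be <= n_intervals")
  combos <- utils::combn(n_intervals, k)
  subsets <- lapply(seq_len(ncol(combos)), function(j) {
    subinterval_columns(combos[, j], n_intervals, grid)
  })
  res <- cpp_subset_rmsecv(X, as.numeric(c), subsets,
                           as.integer(min(A_max, nrow(X) - 2)))
  nm_range <- vapply(seq_len(ncol(combos)), function(j) {
    paste(vapply(combos[, j], function(i) {
      b <- subinterval_bounds(i, n_intervals, grid)
      sprintf("%g-%g", b$lower_nm, b$upper_nm)
    }, ""), collapse = ", ")
  }, "")
  ranking <- data.frame(
    combination = apply(combos, 2, paste, collapse = ","),
    nm_ranges = nm_range,
    n_factors = res$n_factors,
    rmsecv = res$rmsecv,
    stringsAsFactors = FALSE
  )
  # ascending RMSECV; ties -> lexicographically smaller interval index set
  lex_key <- apply(combos, 2, function(z) paste(sprintf("%04d", z),
                                                collapse = ","))
  ord <- order(ranking$rmsecv, lex_key)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  best_idx <- as.integer(strsplit(ranking$combination[1], ",")[[1]])
  structure(
    list(n_intervals = n_intervals, k = k, ranking = ranking,
         best = list(intervals = best_idx,
                     nm_ranges = ranking$nm_ranges[1],
                     n_factors = ranking$n_factors[1],
                     rmsecv = ranking$rmsecv[1]),
         grid = grid),
    class = "interval_combination_result"
  )
}

#' @export
print.interval_combination_result <- function(x, ...) {
  cat(sprintf(
    "<interval_combination_result> %d-of-%d search, %d combinations\n  best: {%s} (%s), %d factors, RMSECV %.5g\n",
    x$k, x$n_intervals, nrow(x$ranking),
    paste(x$best$intervals, collapse = ","), x$best$nm_ranges,
    x$best$n_factors, x$best$rmsecv))
  invisible(x)
}

#' Export a SiPLS ranking as delimited text
#'
#' @param result An `interval_combination_result`.
#' @param path CSV path.
#' @param top_n Number of leading rows to write (default all).
#' @export
write_ranking <- function(result, path, top_n = NULL) {
  stopifnot(inherits(result, "interval_combination_result"))
  r <- result$ranking
  if (!is.null(top_n)) r <- utils::head(r, top_n)
  data.table::fwrite(r, path)
  invisible(path)
}

#' Build the final variable-restricted model
#'
#' Fits a PLS model on the union of the selected subintervals (or an
#' explicit variable mask) with the chosen factor count, recording the mask
#' so full-grid spectra can be predicted directly.
#'
#' @param X_cal Full-grid calibration spectra.
#' @param c_cal Calibration concentrations.
#' @param grid The `wavelength_grid` of `X_cal`.
#' @param selection Integer vector of subinterval indices, or a list with
#'   an `intervals` field (as returned in `sipls_search()$best`).
#' @param n_factors Latent factor count.
#' @param n_intervals Subinterval count the selection refers to.
#' @return A `pls_model` with `variable_mask` set to the selected columns.
#' @export
build_final_model <- function(X_cal, c_cal, grid, selection, n_factors,
                              n_intervals = 20) {
  if (is.list(selection)) selection <- selection$intervals
  selection <- as.integer(selection)
  if (length(selection) == 0) stop("empty interval selection")
  cols <- subinterval_columns(selection, n_intervals, grid)
  pls_fit(as.matrix(X_cal)[, cols, drop = FALSE], c_cal, n_factors,
          variable_mask = cols, n_full = grid$n_points)
}
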