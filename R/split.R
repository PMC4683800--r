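#' Kennard-Stone calibration/validation split
#'
#' Selects a representative calibration subset by the Kennard-Stone max-min
#' procedure on Euclidean distances between spectra: the first two
#' selections are the pair at maximal distance; each subsequent selection
#' maximizes the minimum distance to the already-selected samples. The
#' remaining samples form the validation set. The procedure is fully
#' deterministic: ties are broken toward the lowest original row index
#' (and, for the opening pair, lexicographically smallest index pair).
#'
#' Distances are computed on the spectra exactly as supplied; the workflow
#' calls the splitter on raw spectra before any pretreatment comparison.
#'
#' @param X Spectra matrix (samples x points), >= 3 rows.
#' @param n_cal Requested calibration size: an integer count, or a fraction
#'   in (0, 1) mapped to `round half up(fraction * n)` (93 samples at 2/3
#'   give 62 calibration / 31 validation).
#' @param ids Optional sample identifiers (default row indices as character).
#' @return Object of class `split_result` with `calibration_ids`,
#'   `validation_ids`, `selection_order` (ids in the order chosen) and the
#'   corresponding row indices `calibration_idx`, `validation_idx`.
#' @export
ks_split <- function(X, n_cal, ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples to split")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  stopifnot(length(ids) == n)
  if (n_cal < 1) n_cal <- floor(n_cal * n + 0.5)  # round half up
  n_cal <- as.integer(n_cal)
  if (n_cal < 2 || n_cal >= n) stop("n_cal must satisfy 2 <= n_cal < n")

  D <- unname(as.matrix(stats::dist(X)))
  # opening pair: maximal distance, lexicographic tie-break
  mx <- max(D)
  cand <- which(D == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])

  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- unname(which.max(mind))  # first (lowest-index) max on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  cal <- sort(sel)
  val <- setdiff(seq_len(n), cal)
  structure(
    list(calibration_ids = ids[cal], validation_ids = ids[val],
         selection_order = ids[sel],
         calibration_idx = cal, validation_idx = val),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d validation samples\n",
              length(x$calibration_ids), length(x$validation_ids)))
  invisible(x)
}

#' Persist / reload a split as a two-column id/role table
#'
#' @param split A `split_result`.
#' @param path CSV path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  ord <- match(split$calibration_ids, split$selection_order)
  df <- data.frame(
    sample_id = c(split$calibration_ids, split$validation_ids),
    role = rep(c("calibration", "validation"),
               c(length(split$calibration_ids), length(split$validation_ids))),
    selection_rank = c(ord, rep(NA_integer_, length(split$validation_ids)))
  )
  data.table::fwrite(df, path, na = "NA")
  invisible(path)
}
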