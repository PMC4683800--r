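#' Bundle spectra, grid and process metadata into a dataset
#'
#' A `spectral_dataset` binds an absorbance matrix (samples x wavelengths)
#' to its `wavelength_grid` and to per-sample process metadata: sample id,
#' extraction phase (1, 2 or 3 -- the three sequential water decoctions of
#' the same plant material), sampling time within the phase and, optionally,
#' extract temperature.
#'
#' @param absorbance Numeric matrix, one row per sample, absorbance units.
#' @param grid A `wavelength_grid`; its `n_points` must equal `ncol(absorbance)`.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param phase Integer vector of extraction phase labels in `{1, 2, 3}`.
#' @param time_min Numeric vector of sampling times (minutes into the phase).
#' @param temperature_c Optional numeric vector of extract temperatures (deg C).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(absorbance, grid, sample_ids, phase, time_min,
                             temperature_c = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"), is.matrix(absorbance))
  n <- nrow(absorbance)
  if (ncol(absorbance) != grid$n_points) {
    stop(sprintf("absorbance has %d columns but the grid declares %d points",
                 ncol(absorbance), grid$n_points))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must match rows")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  phase <- as.integer(phase)
  if (length(phase) != n) stop("phase length must match rows")
  bad <- which(!phase %in% 1:3)
  if (length(bad)) {
    stop(sprintf("unknown extraction phase label for sample '%s' (row %d)",
                 sample_ids[bad[1]], bad[1]))
  }
  time_min <- as.numeric(time_min)
  if (length(time_min) != n) stop("time_min length must match rows")
  if (!is.null(temperature_c)) {
    temperature_c <- as.numeric(temperature_c)
    if (length(temperature_c) != n) stop("temperature_c length must match rows")
  }
  rownames(absorbance) <- sample_ids
  structure(
    list(grid = grid, absorbance = absorbance, sample_ids = sample_ids,
         phase = phase, time_min = time_min, temperature_c = temperature_c),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d wavelengths [%g, %g) nm; phases: %s\n",
    nrow(x$absorbance), x$grid$n_points, x$grid$start_nm, x$grid$stop_nm,
    paste(sprintf("%d (n=%d)", 1:3, tabulate(x$phase, 3)), collapse = ", ")
  ))
  invisible(x)
}

#' Per-sample reference concentrations from the wet-lab assays
#'
#' Long-format table of reference concentrations (the HPLC / UV "reference
#' values"): one row per (sample, analyte). Concentrations may be missing
#' (`NA`) where the reference assay was not run or failed for that sample.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param analyte Character vector of analyte names; must be among
#'   `licorice_analytes()`.
#' @param concentration Numeric vector (mg/mL), `NA` allowed, otherwise >= 0.
#' @return A `data.frame` of class `reference_table` with columns
#'   `sample_id`, `analyte`, `concentration_mg_per_ml`.
#' @export
reference_table <- function(sample_ids, analyte, concentration) {
  sample_ids <- as.character(sample_ids)
  analyte <- rep_len(as.character(analyte), length(sample_ids))
  concentration <- as.numeric(concentration)
  stopifnot(length(sample_ids) == length(analyte),
            length(analyte) == length(concentration))
  bad <- setdiff(unique(analyte), licorice_analytes())
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0 where present")
  }
  if (anyDuplicated(paste(sample_ids, analyte))) {
    stop("duplicate (sample_id, analyte) pairs")
  }
  structure(
    data.frame(sample_id = sample_ids, analyte = analyte,
               concentration_mg_per_ml = concentration,
               stringsAsFactors = FALSE),
    class = c("reference_table", "data.frame")
  )
}

#' The four licorice quality markers modelled by the workflow
#'
#' @return Character vector: glycyrrhizic acid, liquiritin, isoliquiritin and
#'   total flavonoids (in that order; isoliquiritin is the low-concentration
#'   hard case).
#' @export
licorice_analytes <- function() {
  c("glycyrrhizic_acid", "liquiritin", "isoliquiritin", "total_flavonoids")
}

#' Read / write a spectral dataset as delimited text
#'
#' Wide CSV layout: metadata columns `sample_id`, `phase`, `time_min`,
#' `temperature_c` first, then one column per wavelength with the wavelength
#' (nm) as header. UTF-8, comma delimited, `.` decimal separator. Values are
#' written with 15 significant digits so a write -> read round trip
#' reproduces the dataset beyond 12 significant digits. The wavelength grid
#' is inferred from the header and validated as uniform.
#'
#' @param dataset A `spectral_dataset`.
#' @param path File path.
#' @return `read_spectra` returns a `spectral_dataset`; `write_spectra`
#'   returns `path` invisibly.
#' @export
write_spectra <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  wl <- grid_wavelengths(dataset$grid)
  meta <- data.table::data.table(
    sample_id = dataset$sample_ids,
    phase = dataset$phase,
    time_min = dataset$time_min,
    temperature_c = if (is.null(dataset$temperature_c)) NA_real_ else
      dataset$temperature_c
  )
  spec <- data.table::as.data.table(dataset$absorbance)
  data.table::setnames(spec, format(wl, digits = 15, trim = TRUE,
                                    scientific = FALSE))
  out <- cbind(meta, spec)
  data.table::fwrite(out, path, sep = ",", dec = ".", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          fill = FALSE)
  meta_cols <- c("sample_id", "phase", "time_min", "temperature_c")
  if (!all(meta_cols %in% names(dt)[1:4])) {
    stop("spectral table must start with columns: ",
         paste(meta_cols, collapse = ", "))
  }
  wl_names <- names(dt)[-(1:4)]
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header at column '", wl_names[which(is.na(wl))[1]], "'")
  }
  if (length(wl) < 2) stop("need at least two spectral columns")
  steps <- diff(wl)
  if (any(steps <= 0)) {
    stop("wavelengths must be strictly increasing; violation after ",
         wl[which(steps <= 0)[1]], " nm")
  }
  if (diff(range(steps)) > 1e-6 * steps[1]) {
    stop("wavelength grid is not uniform")
  }
  step <- steps[1]
  grid <- make_grid(wl[1], wl[length(wl)] + step, step)
  if (grid$n_points != length(wl)) {
    stop(sprintf("inferred grid has %d points but %d spectral columns found",
                 grid$n_points, length(wl)))
  }
  X <- as.matrix(dt[, -(1:4), with = FALSE])
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  temp <- dt$temperature_c
  if (all(is.na(temp))) temp <- NULL
  spectral_dataset(X, grid, dt$sample_id, dt$phase, dt$time_min, temp)
}

#' Read / write a reference concentration table
#'
#' Long CSV with columns `sample_id`, `analyte`, `concentration_mg_per_ml`;
#' missing reference values written as `NA`.
#'
#' @param refs A `reference_table`.
#' @param path File path.
#' @export
write_references <- function(refs, path) {
  stopifnot(inherits(refs, "reference_table"))
  data.table::fwrite(as.data.frame(refs), path, sep = ",", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  need <- c("sample_id", "analyte", "concentration_mg_per_ml")
  if (!all(need %in% names(dt))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  reference_table(dt$sample_id, dt$analyte, dt$concentration_mg_per_ml)
}

#' Pair spectra with reference concentrations for one analyte
#'
#' Restricts a dataset to the samples holding a present (non-`NA`) reference
#' value for `analyte`, preserving the dataset's sample order, and returns
#' the paired spectra matrix and concentration vector. Samples without a
#' usable reference are reported in `dropped`.
#'
#' @param dataset A `spectral_dataset`.
#' @param refs A `reference_table`.
#' @param analyte One analyte name.
#' @return List with `X` (spectra), `c` (mg/mL), `ids`, `phase`, `time_min`
#'   and `dropped` (ids of dataset samples without a present reference).
#' @export
align_dataset <- function(dataset, refs, analyte) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(refs, "reference_table"))
  analyte <- match.arg(analyte, licorice_analytes())
  sub <- refs[refs$analyte == analyte & !is.na(refs$concentration_mg_per_ml), ]
  conc <- stats::setNames(sub$concentration_mg_per_ml, sub$sample_id)
  keep <- dataset$sample_ids %in% names(conc)
  if (!any(keep)) {
    stop("no sample of the dataset has a present reference value for ", analyte)
  }
  ids <- dataset$sample_ids[keep]
  list(
    X = dataset$absorbance[keep, , drop = FALSE],
    c = unname(conc[ids]),
    ids = ids,
    phase = dataset$phase[keep],
    time_min = dataset$time_min[keep],
    dropped = dataset$sample_ids[!keep]
  )
}
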