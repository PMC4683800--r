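#' Published phase-wise relative errors
#'
#' Loads the per-sample relative errors (percent) of the NIR predictions
#' against the reference assay in the three extraction phases, as printed
#' in the published assessment table the workflow follows, together with
#' the printed per-phase means. `NA` marks samples not selected into that
#' analyte's validation set. See `inst/extdata/README.md` for known
#' inconsistencies between some printed means and their own columns.
#'
#' @return List with `per_sample` and `printed_means` data.frames.
#' @export
published_phase_errors <- function() {
  per_sample <- utils::read.csv(
    system.file("extdata", "published_phase_relative_errors.csv",
                package = "licoriceNIR"),
    stringsAsFactors = FALSE)
  printed <- utils::read.csv(
    system.file("extdata", "published_phase_mean_relative_errors.csv",
                package = "licoriceNIR"),
    stringsAsFactors = FALSE)
  list(per_sample = per_sample, printed_means = printed)
}
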