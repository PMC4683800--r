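#' Construct a uniform wavelength grid
#'
#' NIR process spectra in this package live on a uniform wavelength grid.
#' The grid uses the half-open convention `[start_nm, stop_nm)`: the grid
#' covers `start_nm, start_nm + step_nm, ...` up to but excluding `stop_nm`.
#' An 800--2200 nm grid at 0.5 nm increment therefore holds exactly 2800
#' variables, matching the variable count used throughout the workflow
#' (a closed grid would hold 2801 fenceposts).
#'
#' @param start_nm First wavelength (nm), included.
#' @param stop_nm End of the span (nm), excluded.
#' @param step_nm Wavelength increment (nm), must divide the span exactly.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `n_points`.
#' @examples
#' g <- make_grid(800, 2200, 0.5)
#' g$n_points # 2800
#' @export
make_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (stop_nm <= start_nm) stop("stop_nm must exceed start_nm")
  span <- stop_nm - start_nm
  n <- span / step_nm
  if (abs(n - round(n)) > 1e-9 * max(1, n)) {
    stop(sprintf(
      "step_nm (%g) does not divide the span %g-%g nm: remainder %g nm",
      step_nm, start_nm, stop_nm, span - floor(n) * step_nm
    ))
  }
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         n_points = as.integer(round(n))),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> [%g, %g) nm, step %g nm, %d points\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n_points))
  invisible(x)
}

#' Wavelength vector of a grid
#'
#' @param grid A `wavelength_grid`.
#' @return Numeric vector of length `grid$n_points`; wavelength of 1-based
#'   index `j` is `start_nm + (j - 1) * step_nm`.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + (seq_len(grid$n_points) - 1) * grid$step_nm
}

# Point-index widths of an equidistant partition of n points into k intervals.
# When k does not divide n, trailing intervals absorb one extra point each
# (rightmost-first), keeping widths within one point of equal.
interval_widths <- function(n_points, n_intervals) {
  base <- n_points %/% n_intervals
  rem <- n_points %% n_intervals
  widths <- rep.int(base, n_intervals)
  if (rem > 0) widths[(n_intervals - rem + 1):n_intervals] <- base + 1L
  widths
}

#' Bounds of one equidistant spectral subinterval
#'
#' Splits the grid into `n_intervals` equidistant subintervals, the
#' partition used by synergy interval PLS (20 subintervals of 70 nm on the
#' 800--2200 nm / 0.5 nm grid). Interval `i` spans
#' `[start + (i-1) * w, start + i * w)` nm where `w = span / n_intervals`.
#' When the point count is not divisible, trailing intervals absorb one
#' extra point each (rightmost-first).
#'
#' @param index 1-based subinterval index.
#' @param n_intervals Number of equidistant subintervals.
#' @param grid A `wavelength_grid`.
#' @return List with `lower_nm`, `upper_nm` (half-open nm bounds) and
#'   `first_index`, `last_index` (1-based point-index range).
#' @examples
#' g <- make_grid(800, 2200, 0.5)
#' subinterval_bounds(4, 20, g) # 1010-1080 nm
#' @export
subinterval_bounds <- function(index, n_intervals, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  index <- as.integer(index)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1 || n_intervals > grid$n_points) {
    stop("n_intervals must be between 1 and the number of grid points")
  }
  if (index < 1 || index > n_intervals) {
    stop(sprintf("interval index %d out of range 1..%d", index, n_intervals))
  }
  widths <- interval_widths(grid$n_points, n_intervals)
  last <- cumsum(widths)
  first <- c(1L, last[-n_intervals] + 1L)
  list(
    lower_nm = grid$start_nm + (first[index] - 1L) * grid$step_nm,
    upper_nm = grid$start_nm + last[index] * grid$step_nm,
    first_index = first[index],
    last_index = last[index]
  )
}

#' Point indices covered by a set of subintervals
#'
#' @param indices Integer vector of 1-based subinterval indices.
#' @inheritParams subinterval_bounds
#' @return Sorted integer vector of 1-based grid point indices.
#' @export
subinterval_columns <- function(indices, n_intervals, grid) {
  cols <- lapply(indices, function(i) {
    b <- subinterval_bounds(i, n_intervals, grid)
    seq.int(b$first_index, b$last_index)
  })
  sort(unique(unlist(cols)))
}

#' Thin a spectral grid by block averaging
#'
#' Averages `factor` adjacent wavelength points into one, producing a
#' coarser grid with `n_points / factor` variables. Used as a fast mode for
#' exhaustive variable-selection searches; the averaged grid keeps the
#' half-open span so equidistant subinterval bounds in nm are unchanged.
#'
#' @param X Spectra matrix (samples x points).
#' @param grid The `wavelength_grid` of `X`.
#' @param factor Integer thinning factor; must divide `grid$n_points`.
#' @return List with thinned `X` and the new `grid`.
#' @export
thin_grid <- function(X, grid, factor) {
  stopifnot(inherits(grid, "wavelength_grid"))
  factor <- as.integer(factor)
  if (factor < 1) stop("thinning factor must be >= 1")
  if (grid$n_points %% factor != 0) {
    stop("thinning factor must divide the number of grid points")
  }
  if (factor == 1L) return(list(X = X, grid = grid))
  n_new <- grid$n_points %/% factor
  grp <- rep(seq_len(n_new), each = factor)
  Xt <- t(rowsum(t(X), grp, reorder = TRUE)) / factor
  dimnames(Xt) <- list(rownames(X), NULL)
  list(X = Xt, grid = make_grid(grid$start_nm, grid$stop_nm,
                                grid$step_nm * factor))
}
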