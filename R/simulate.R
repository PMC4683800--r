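#' Pure-component spectrum specification
#'
#' A pure-component spectrum is modelled as a sum of Gaussian absorption
#' bands, the standard stand-in for smooth NIR overtone/combination bands
#' when measured pure spectra are unavailable. Heights are unit-concentration
#' absorptivities (absorbance mL/mg), so mixture spectra follow Beer-Lambert
#' linearity in concentration.
#'
#' @param analyte Analyte name.
#' @param bands Matrix or data.frame with columns `center_nm`, `width_nm`,
#'   `height` (one row per band); widths > 0, heights >= 0, at least one band.
#' @return Object of class `pure_component_spec`.
#' @export
pure_component_spec <- function(analyte, bands) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center_nm", "width_nm", "height") %in% names(bands)))
  if (nrow(bands) < 1) stop("at least one band per analyte")
  if (any(bands$width_nm <= 0)) stop("band widths must be > 0")
  if (any(bands$height < 0)) stop("band heights must be >= 0")
  structure(list(analyte = analyte, bands = bands),
            class = "pure_component_spec")
}

#' Evaluate a pure-component spectrum on a grid
#'
#' @param spec A `pure_component_spec`.
#' @param grid A `wavelength_grid`.
#' @return Non-negative numeric vector of length `grid$n_points`:
#'   `sum_bands height * exp(-(lambda - center)^2 / (2 width^2))`.
#' @export
pure_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "pure_component_spec"))
  wl <- grid_wavelengths(grid)
  out <- numeric(length(wl))
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    out <- out + b$height * exp(-(wl - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  out
}

#' First-order extraction kinetics specification
#'
#' Within each decoction phase the dissolved concentration follows
#' `c(t) = c_max * (1 - exp(-k * max(0, t - t_lag)))`, restarting from zero
#' when fresh water is added for the next phase. `c_max` decreases across
#' phases (diminishing yield from the partially spent plant material) and
#' `t_lag` models the heating-up delay before extraction proceeds.
#'
#' @param analyte Analyte name.
#' @param c_max Length-3 numeric, plateau concentration (mg/mL) per phase,
#'   non-increasing across phases.
#' @param rate_k Length-3 numeric, first-order rate (1/min) per phase, > 0.
#' @param t_lag Lag time (min) before extraction starts within a phase.
#' @return Object of class `kinetic_profile_spec`.
#' @export
kinetic_profile_spec <- function(analyte, c_max, rate_k, t_lag = 0) {
  stopifnot(length(c_max) == 3, length(rate_k) == 3)
  if (any(c_max < 0)) stop("c_max must be >= 0")
  if (is.unsorted(rev(c_max))) stop("c_max must be non-increasing across phases")
  if (any(rate_k <= 0)) stop("rate_k must be > 0")
  structure(list(analyte = analyte, c_max = c_max, rate_k = rate_k,
                 t_lag = t_lag),
            class = "kinetic_profile_spec")
}

#' Concentration profile along a sampling schedule
#'
#' @param kinetics A `kinetic_profile_spec`.
#' @param times Numeric vector of sampling times (min into the phase).
#' @param phase Integer vector (same length) of phase labels in 1..3.
#' @return Numeric vector of concentrations (mg/mL).
#' @export
concentration_profiles <- function(kinetics, times, phase) {
  stopifnot(inherits(kinetics, "kinetic_profile_spec"),
            length(times) == length(phase))
  if (any(times < 0)) stop("times must be non-negative")
  phase <- as.integer(phase)
  stopifnot(all(phase %in% 1:3))
  dt <- pmax(0, times - kinetics$t_lag)
  kinetics$c_max[phase] * (1 - exp(-kinetics$rate_k[phase] * dt))
}

#' Default pure-component band sets
#'
#' Fictional but fixed Gaussian band placements with distinct centers per
#' analyte. Amplitudes reproduce the study design's hard case: isoliquiritin
#' is present at roughly 1/20 of the glycyrrhizic acid level, so its spectral
#' contribution is about 20x weaker and its calibration correspondingly
#' harder.
#'
#' @return Named list of `pure_component_spec`, one per
#'   [licorice_analytes()] entry.
#' @export
default_component_specs <- function() {
  list(
    glycyrrhizic_acid = pure_component_spec("glycyrrhizic_acid", data.frame(
      center_nm = c(1045, 1190, 1450, 1725),
      width_nm  = c(18,   35,   45,   22),
      height    = c(0.030, 0.050, 0.080, 0.060)
    )),
    liquiritin = pure_component_spec("liquiritin", data.frame(
      center_nm = c(970, 1315, 1520, 1745),
      width_nm  = c(20,  28,   40,   25),
      height    = c(0.060, 0.090, 0.070, 0.110)
    )),
    isoliquiritin = pure_component_spec("isoliquiritin", data.frame(
      center_nm = c(1250, 1460, 1680),
      width_nm  = c(22,   30,   24),
      height    = c(0.070, 0.060, 0.090)
    )),
    total_flavonoids = pure_component_spec("total_flavonoids", data.frame(
      center_nm = c(1130, 1535, 1790, 2050),
      width_nm  = c(30,   28,   26,   40),
      height    = c(0.040, 0.065, 0.055, 0.035)
    ))
  )
}

#' Default extraction kinetics
#'
#' Plateau levels chosen to match the concentration windows the reference
#' assays report for pilot-plant licorice decoction: total flavonoids up to
#' about 1.9 mg/mL, glycyrrhizic acid slightly above, liquiritin an order of
#' magnitude lower and isoliquiritin lowest of all (about 1/20 of
#' glycyrrhizic acid). Rates differ per analyte and per phase so that the
#' four concentration time courses are linearly independent.
#'
#' @return Named list of `kinetic_profile_spec`.
#' @export
default_kinetic_specs <- function() {
  list(
    glycyrrhizic_acid = kinetic_profile_spec(
      "glycyrrhizic_acid", c_max = c(2.40, 1.15, 0.45),
      rate_k = c(0.030, 0.026, 0.022), t_lag = 5),
    liquiritin = kinetic_profile_spec(
      "liquiritin", c_max = c(0.75, 0.36, 0.14),
      rate_k = c(0.045, 0.038, 0.030), t_lag = 4),
    isoliquiritin = kinetic_profile_spec(
      "isoliquiritin", c_max = c(0.110, 0.048, 0.018),
      rate_k = c(0.060, 0.050, 0.040), t_lag = 4),
    total_flavonoids = kinetic_profile_spec(
      "total_flavonoids", c_max = c(1.90, 0.88, 0.33),
      rate_k = c(0.035, 0.030, 0.025), t_lag = 5)
  )
}

#' Generator configuration for synthetic extraction spectra
#'
#' Describes the stochastic model of one online NIR monitoring run of a
#' three-phase licorice decoction: Beer-Lambert mixture spectra over
#' Gaussian pure-component bands, a dominant water band near 1950 nm,
#' per-spectrum multiplicative gain and additive offset (scatter from
#' particulates/bubbles), a temperature-coupled linear baseline drift, and
#' heteroscedastic detector noise with extra variance in the noisy
#' 2000--2200 nm combination region. Defaults emulate 93 process samples
#' (40/30/23 per phase, denser early sampling) on the 800--2200 nm / 0.5 nm
#' grid.
#'
#' @param grid A `wavelength_grid`.
#' @param n_per_phase Integer length-3 sample counts per phase (each >= 2).
#' @param components List of `pure_component_spec`.
#' @param kinetics Named list of `kinetic_profile_spec` (same analytes).
#' @param water_band Numeric `c(center_nm, width_nm, height)` of the solvent
#'   band; absorbance at unit water activity.
#' @param baseline Numeric `c(offset_au, per_degC_au)`: wavelength-linear
#'   drift whose amplitude is `offset_au + per_degC_au * (T - 60)`.
#' @param gain_sd Per-spectrum multiplicative gain sd (gain ~ 1 + N(0, sd)).
#' @param offset_sd Per-spectrum additive offset sd (absorbance units).
#' @param noise_sd Base white-noise sd per point (absorbance units).
#' @param noise_extra_sd Additional noise sd applied in `noisy_region_nm`.
#' @param noisy_region_nm Length-2 nm range of the high-noise region.
#' @param assay_rel_sd Relative sd of the reference-assay error applied to
#'   the true concentrations when building the reference table.
#' @param assay_abs_sd Absolute sd (mg/mL) of the reference-assay error
#'   floor, independent of concentration. This is what makes the
#'   low-content analyte (isoliquiritin) genuinely harder: near the assay's
#'   quantification limit the error does not shrink with the concentration.
#' @param phase_duration_min Duration of each decoction phase (min).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(grid = make_grid(800, 2200, 0.5),
                             n_per_phase = c(40L, 30L, 23L),
                             components = default_component_specs(),
                             kinetics = default_kinetic_specs(),
                             water_band = c(1950, 55, 1.20),
                             baseline = c(0.02, 0.0015),
                             gain_sd = 0.02,
                             offset_sd = 0.01,
                             noise_sd = 0.002,
                             noise_extra_sd = 0.008,
                             noisy_region_nm = c(2000, 2200),
                             assay_rel_sd = 0.01,
                             assay_abs_sd = 0.002,
                             phase_duration_min = 150) {
  stopifnot(inherits(grid, "wavelength_grid"), length(n_per_phase) == 3)
  n_per_phase <- as.integer(n_per_phase)
  if (any(n_per_phase < 2)) stop("need at least 2 samples per phase")
  if (any(c(gain_sd, offset_sd, noise_sd, noise_extra_sd, assay_rel_sd,
            assay_abs_sd) < 0)) {
    stop("all standard deviations must be >= 0")
  }
  if (!identical(sort(names(components)), sort(names(kinetics)))) {
    stop("components and kinetics must describe the same analytes")
  }
  structure(
    list(grid = grid, n_per_phase = n_per_phase, components = components,
         kinetics = kinetics, water_band = water_band, baseline = baseline,
         gain_sd = gain_sd, offset_sd = offset_sd, noise_sd = noise_sd,
         noise_extra_sd = noise_extra_sd, noisy_region_nm = noisy_region_nm,
         assay_rel_sd = assay_rel_sd, assay_abs_sd = assay_abs_sd,
         phase_duration_min = phase_duration_min),
    class = "generator_config"
  )
}

# Sampling schedule: denser early sampling in phase 1 (contents change
# rapidly while heating/boiling), progressively sparser in phases 2 and 3.
sampling_schedule <- function(config) {
  d <- config$phase_duration_min
  n <- config$n_per_phase
  # quadratic warp concentrates phase-1 samples early
  t1 <- d * (seq_len(n[1]) / n[1])^1.4
  t2 <- d * seq_len(n[2]) / n[2]
  t3 <- d * seq_len(n[3]) / n[3]
  data.frame(
    phase = rep(1:3, times = n),
    time_min = c(t1, t2, t3)
  )
}

#' Simulate one online NIR extraction run
#'
#' Draws a full synthetic dataset from a [generator_config()]: true
#' concentrations from the phase-wise first-order kinetics, absorbance rows
#' `gain_i * (sum_a c_ia pure_a + water) + baseline_i + offset_i + noise_i`,
#' and a reference table equal to the true concentrations perturbed by the
#' stated relative assay error. Fully reproducible from `seed`.
#'
#' @param config A `generator_config`.
#' @param seed Integer RNG seed governing all stochastic draws.
#' @return List with `dataset` (a `spectral_dataset`), `references`
#'   (a `reference_table`, assay noise included) and `truth` (matrix of the
#'   noiseless true concentrations, samples x analytes).
#' @export
simulate_dataset <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  grid <- config$grid
  wl <- grid_wavelengths(grid)
  sched <- sampling_schedule(config)
  n <- nrow(sched)
  analytes <- names(config$components)

  # true concentration matrix (samples x analytes)
  Ctrue <- sapply(analytes, function(a) {
    concentration_profiles(config$kinetics[[a]], sched$time_min, sched$phase)
  })
  Ctrue <- matrix(Ctrue, nrow = n,
                  dimnames = list(NULL, analytes))

  # pure-component basis + solvent band
  P <- sapply(analytes, function(a) pure_spectrum(config$components[[a]], grid))
  water <- config$water_band[3] *
    exp(-(wl - config$water_band[1])^2 / (2 * config$water_band[2]^2))

  signal <- Ctrue %*% t(P) + matrix(water, n, grid$n_points, byrow = TRUE)

  # temperature: heating ramp to boiling, then hold
  temperature <- pmin(100, 25 + 2.5 * sched$time_min)

  gain <- 1 + stats::rnorm(n, 0, config$gain_sd)
  offset <- stats::rnorm(n, 0, config$offset_sd)
  ramp <- (wl - grid$start_nm) / (grid$stop_nm - grid$start_nm)
  drift_amp <- config$baseline[1] + config$baseline[2] * (temperature - 60)
  baseline <- outer(drift_amp, ramp)

  noise_sd_vec <- rep(config$noise_sd, grid$n_points)
  noisy <- wl >= config$noisy_region_nm[1] & wl < config$noisy_region_nm[2]
  noise_sd_vec[noisy] <- sqrt(config$noise_sd^2 + config$noise_extra_sd^2)
  noise <- matrix(stats::rnorm(n * grid$n_points), n, grid$n_points) *
    matrix(noise_sd_vec, n, grid$n_points, byrow = TRUE)

  X <- signal * gain + baseline + offset + noise

  ids <- sprintf("S%02d_P%d", seq_len(n), sched$phase)
  dataset <- spectral_dataset(X, grid, ids, sched$phase, sched$time_min,
                              temperature)

  na <- length(analytes)
  assay <- Ctrue * (1 + matrix(stats::rnorm(n * na, 0, config$assay_rel_sd),
                               n, na)) +
    matrix(stats::rnorm(n * na, 0, config$assay_abs_sd), n, na)
  assay[assay < 0] <- 0
  refs <- reference_table(
    sample_ids = rep(ids, times = length(analytes)),
    analyte = rep(analytes, each = n),
    concentration = as.vector(assay)
  )
  list(dataset = dataset, references = refs, truth = Ctrue)
}
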