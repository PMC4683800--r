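---
title: "Methods: NIR multivariate calibration for multi-phase licorice extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR multivariate calibration for multi-phase licorice extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(licoriceNIR)
```

## The problem

Water decoction of licorice (*Radix Glycyrrhizae*) is run as three
sequential extraction phases on the same plant material. Process analytical
technology asks for inline quantification of the quality markers --
glycyrrhizic acid, liquiritin, isoliquiritin and total flavonoids -- from
near-infrared (NIR) absorbance spectra collected through a fiber-optic flow
cell, with high-performance liquid chromatography (HPLC) and UV
spectrophotometry supplying the reference concentrations used to calibrate
and validate the models.

`licoriceNIR` implements that chemometric workflow end to end:

1. sample-set partitioning (Kennard--Stone),
2. spectral pretreatment comparison (Savitzky--Golay smoothing and
   derivatives, SNV, MSC, orthogonal signal correction, wavelet denoising,
   vector normalization),
3. PLS1 calibration with leave-one-out cross-validation and PRESS-based
   latent-factor selection,
4. wavelength selection by moving-window PLS (MWPLS) and synergy interval
   PLS (SiPLS),
5. phase-wise assessment: relative errors, an F test against the reference
   method, and a multivariate detection limit (MDL).

Because no raw pilot-plant data are publicly available, the package ships a
synthetic-data generator with the statistical structure the analysis
assumes, so every stage is exercised by tests without any download.

## The spectral model and its containers

Spectra live on a uniform wavelength grid with the **half-open convention**
`[start, stop)`: 800--2200 nm at 0.5 nm holds exactly 2800 variables. This
convention was chosen because the workflow's variable count (2800) and its
20 equidistant subintervals of exactly 70 nm (1010--1080, 1290--1360, ...)
are only mutually consistent on a half-open grid; a closed grid would have
2801 fenceposts and ragged intervals. When the point count is not divisible
by the interval count, trailing intervals absorb one extra point each
(rightmost-first), a deterministic rule that keeps widths within one point
of equal.

A `spectral_dataset` binds the absorbance matrix to its grid and to process
metadata (extraction phase 1/2/3, sampling time, temperature); a
`reference_table` holds the per-sample assay concentrations in mg/mL, with
`NA` where the assay was not run. `align_dataset()` pairs the two per
analyte, dropping samples without a present reference -- this is why each
analyte's calibration can see a slightly different sample list, mirroring
the "NA samples" of phase-wise assessment tables.

## Partial least squares

PLS1 is fitted by NIPALS with mean-centering of both blocks and **no
variance scaling**: absorbance channels share a unit, and scaling would
inflate the noise-only channels. With a single response the NIPALS inner
loop closes in one step per factor, and the fast kernels (RcppArmadillo)
accumulate the regression vector for every factor count `1..A` in one pass,
which makes exhaustive cross-validated searches cheap.

Factor selection minimizes PRESS under leave-one-out cross-validation, with
centering recomputed in every fold so no held-out information leaks in.
RMSECV uses the denominator `n` (the RMSE formula with all `n` LOO
residuals). Ties in PRESS go to the smaller factor count; "tie" includes a
relative band of 1e-8 and an absolute floor of 1e-10 times the response sum
of squares -- without that band, exactly-fitting models (noiseless rank-1
data) would pick extra factors on PRESS differences of order 1e-30. `A_max`
defaults to 10 and is capped per model at `min(A_max, p - 1, n - 2)` for a
model with `p` variables.

`R^2` is `1 - SSE/SST` (not a squared correlation); vendor packages differ
on this point, so the definition is fixed and documented.

## Pretreatment ladder and the selection rule

Each pretreatment is a fit/apply pair: MSC stores the calibration mean
spectrum, OSC stores its weight/loading pairs, and every other transform is
a stateless row operation, so fitted pipelines never consume
validation-set statistics. Defaults the underlying workflow leaves
unstated, decided here:

* Savitzky--Golay polynomial order: 2 for smoothing and first derivative, 3
  for the second derivative (common chemometric practice); derivatives are
  divided by the grid step so they are per-nm and grid-invariant. Edges are
  handled by refitting the polynomial on the truncated window.
* OSC: one component by default, implemented as score extraction from the
  leading principal direction, exact orthogonalization against the centred
  response, and a minimum-norm weight vector solving `X w = t` -- this
  reproduces scores exactly on the calibration set and makes the correction
  idempotent. Note a property worth stating honestly: OSC leaves each
  column's covariance with the response unchanged while removing variance,
  so column-response *correlations* can only grow; what OSC buys is fewer
  PLS factors, not decorrelation.
* Wavelet denoising ("WDS"): Daubechies-4, decomposition depth
  `floor(log2(p)) - 4`, soft universal threshold `sigma * sqrt(2 log n)`
  with `sigma` from the median absolute deviation of the finest details.
  The DWT is implemented in-package (periodic convolution after symmetric
  right-padding) because no wavelet package is available in the target
  environment.
* "Normalization" means unit Euclidean norm per spectrum.

The working pretreatment is chosen by a **veto-then-rank** rule
(`select_pretreatment()`): candidates whose RMSEP exceeds twice the best
candidate RMSEP are vetoed, then the lowest RMSECV wins, ties falling to
the simpler (earlier ladder) method. The veto encodes the classic OSC
failure mode -- best cross-validation, collapsed independent prediction --
as a deterministic rule; the guard factor 2 is configurable.

## Wavelength selection

**MWPLS** slides a window of `H` variables (odd `H`, default 13--41, step
one variable) and records the PRESS-optimal RMSECV per window. A window set
is only *informative* if its best RMSECV is strictly below the
full-spectrum benchmark; otherwise the verdict is "inappropriate", the
negative finding the method is expected to produce on analytes whose
information is spread across the spectrum.

**SiPLS** splits the grid into 20 equidistant subintervals and evaluates
all `C(20, 3) = 1140` three-interval joint models exhaustively, choosing
factors per combination by lowest PRESS and ranking combinations by
RMSECV (ties: lexicographically smaller interval set). nm ranges in reports
are single-sourced through `subinterval_bounds()`. For tests and quick
runs, `thin_grid()` block-averages adjacent points (default pipeline factor
4: 2800 to 700 variables) -- thinning changes no interval boundary because
the nm span is preserved.

## Phase-wise assessment

Relative error is `|predicted - reference| / reference * 100`; phase means
average the present values only and are displayed at two decimals with
round-half-up (full precision retained internally). The F test regresses
predictions on reference values and reports
`F = SSR / (SSE / (n - 2))` with df `(1, n - 2)`; at `alpha = 0.01` and
`n = 93` the critical value is 6.92, the closest standard candidate to the
6.90 quoted in printed F tables. The MDL uses the pseudounivariate
variant: predictions are regressed on reference concentrations over the
calibration set and
`MDL = Delta(alpha, beta) * s0 / slope`, where `s0` is the standard error
of the estimated response at zero concentration and
`Delta(0.05, 0.05) ~ 3.30`; ppm figures assume extract density 1 g/mL
(1 mg/mL = 1000 ppm). Both conventions are recorded in the result objects.

## What the synthetic generator emulates -- and what it does not

`simulate_dataset()` draws one monitoring run: 93 samples (40/30/23 per
phase, denser early sampling while contents change fastest), Beer--Lambert
mixture spectra over fixed Gaussian pure-component bands, a dominant water
band at 1950 nm, per-spectrum multiplicative gain (sd 0.02) and additive
offset (sd 0.01 AU) for particulate/bubble scatter, a temperature-coupled
linear baseline drift, heteroscedastic detector noise (0.002 AU baseline
with an extra 0.008 AU in the noisy 2000--2200 nm combination region), and
phase-wise first-order extraction kinetics with diminishing plateaus.
Concentration windows match the reference assays' reported ranges (total
flavonoids up to ~1.9 mg/mL; isoliquiritin lowest at ~1/20 of glycyrrhizic
acid). Reference values carry 1 % relative assay error plus an absolute
floor of 0.002 mg/mL; the floor is what makes the low-content analyte
genuinely the hardest model, since a purely relative error scales away with
the concentration range.

Not emulated: instrument physics (radiative transfer, detector
nonlinearity), temperature-dependent band shifts, drifting pure-component
shapes, or real band assignments -- the band placements are fictional but
fixed. A green test on synthetic data therefore establishes that the
*algorithms* behave as specified under the assumed data-generating model,
not that the shipped defaults would quantify real licorice extract.

## Numerical choices and degenerate inputs

* Kennard--Stone is deterministic: the opening pair is the global
  max-distance pair (lexicographic tie-break), later picks maximize the
  min-distance to the selected set with ties to the lowest original index.
  Fractions map to counts by round-half-up (93 x 2/3 = 62). The splitter
  runs on raw spectra by default; pretreated space is a caller choice.
* SNV, MSC and normalization reject near-constant/zero rows by name rather
  than emitting NaN; OSC rejects a zero-variance response.
* An empty validation set reports RMSEP as absent (`NA`), never zero.
* Perfectly collinear F-test inputs report `F = Inf`, significant.
* All simulation and workflow randomness flows from a single integer seed;
  reports regenerate byte-identically from the same config and seed.

## Known limitations

* PLS1 only -- each analyte is modelled separately (no PLS2), matching the
  workflow's design.
* Cross-validation is leave-one-out everywhere; segmented CV is not
  implemented.
* The MWPLS scan at full 0.5 nm resolution with the whole `H` ladder is
  compute-heavy in plain R terms (hundreds of thousands of PLS fits); the
  C++ kernels make it feasible, and the pipeline's default 4x grid
  thinning is recommended for interactive use.
* OSC is the single-component Wold-style variant; EMSC, detrending and
  piecewise MSC are out of scope.
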