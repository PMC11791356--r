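---
title: "Quantifying evoked dopamine release from nanosensor movies"
author: "darelease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying evoked dopamine release from nanosensor movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darelease)
```

## The measurement problem

Single-walled carbon nanotubes wrapped in (GT)₆ single-stranded DNA form a
near-infrared fluorescent dopamine nanosensor: fluorescence in the NIR-II
window turns on reversibly when dopamine binds the DNA corona, with
nanosecond binding kinetics and no photobleaching. Coated over a
dopaminergic culture and imaged at 5 frames/s (0.74 μm pixels, 200 ms
exposure), the sensor layer converts electrically evoked dopamine release
into transient, spatially localized fluorescence increases — *hotspots* —
around axonal varicosities. The analysis task is to turn a raw movie into
per-hotspot quantities (peak ΔF/F₀, area, temporal FWHM), per-field-of-view
summaries, clearance kinetics, and group comparisons (here: control vs
*GBA1*-mutant Parkinson's disease cultures at early/late differentiation).

No raw recordings ship with the package. Instead a seeded generator
(`simulate_movie()`) produces movies with the same statistical structure,
with exact ground truth, so each pipeline stage is testable end to end.

## Sensor model

`da_response()` is a one-site Langmuir isotherm,
ΔF/F₀(c) = ΔFmax·c/(c+Kd), with defaults Kd = 15 μM and ΔFmax = 6.44.
ΔFmax is *derived*, not printed anywhere: inverting the isotherm at the
sensor's working point (560 % enhancement at 100 μM with Kd = 15 μM) gives
5.6·(100+15)/100 = 6.44. A Hill exponent is available (`hill`) but defaults
to 1 because the calibration reports a single Kd with no cooperativity.

`fit_isotherm()` uses Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), unweighted unless replicate standard deviations are
present (then inverse-variance). Initialisation: ΔFmax₀ = max response,
Kd₀ = concentration nearest half of ΔFmax₀. Degenerate tables (all-zero
responses, unbracketed half-saturation) return a non-converged fit report
rather than an error. On noiseless model data the round trip recovers the
generating parameters to better than 10⁻⁶ relative; at 5 % multiplicative
noise the Kd estimate is within ±20 % for the large majority of seeds
(Monte-Carlo over 100 seeds), so tests assert the median over a fixed seed
set.

Solution-phase calibration reads ΔF/F₀ at the emission peak of the (9,4)
chirality near 1130 nm; `peak_response()` therefore defaults its search
window to 1100–1160 nm. The 560 % working point is quoted at 1200 nm while
the calibration curve uses the 1130 nm peak; the window is a parameter
precisely because the two conventions coexist.

## Baseline and ΔF/F₀

`estimate_baseline()` implements iterated low-pass/clip baselining: per
pixel, repeat `n_rounds` times {moving-average smooth over `window_frames`;
replace samples *above* the smoothed curve by it}. The asymmetric clip
means positive transients cannot inflate F₀ while slow drift is tracked;
the final F₀ is the temporal mean of the last clipped, smoothed trace, and
a constant trace is an exact fixed point.

Defaults: window 61 frames (≈12 s at 5 fps), 3 rounds. The window must be
longer than the *whole* transient — the 5-s stimulus plus a few seconds of
clearance decay — or the tail reads as drift; 61 frames keeps the residual
baseline contamination of a one-site movie below ≈2 %, where a 31-frame
window (longer than the stimulus alone) leaves ≈3.5 %. Both are exposed in
the configuration.

`compute_dff()` divides by F₀ wherever the baseline is valid. Pixels with
F₀ at or below max(`floor`, 1 % of the median baseline) are masked `NA`
(never silently 0): a relative-to-median rule guards dark background
without masking anything in a uniformly illuminated field.

## Hotspot detection

`detect_hotspots()` composes five documented stages; every rule below is
mirrored by a naive brute-force reference implementation in the test suite
that must agree exactly on small movies.

1. **Score map** (`score_map()`): per pixel, the maximum first difference
   (× frame rate) of the ΔF/F₀ trace inside the evaluation window
   (stimulation start → end + 2 s pad, reflecting release/diffusion lag).
   The identical statistic over pre-stimulus frames gives the noise
   reference.
2. **Seeds** (`find_seeds()`): 8-neighborhood local maxima above
   median + `snr_min`·MAD of the pre-stimulus scores, greedily thinned to a
   minimum separation (default 8 px ≈ 5.9 μm — one typical hotspot
   diameter; two release sites closer than that are not resolvable as
   separate hotspots). Ordering is descending score with (row, col)
   tie-breaks, so results are deterministic.
3. **ROI growth** (`grow_roi()`): 8-connected flood from the seed over the
   per-pixel *peak map* (maximum ΔF/F₀ in the window, computed on traces
   lightly smoothed with a 3-frame moving average — `peak_smoothing` —
   because an unsmoothed max over noisy frames is biased upward and dilates
   ROIs). Pixels join if their peak is ≥ `roi_growth_fraction` (default
   0.5, the half-max region) of the seed's peak *and* above the
   pre-stimulus noise floor of the peak map; growth is capped at
   `max_radius_um` (12 μm) so a flood cannot chain across adjacent sites.
   On noiseless data the floor is zero and the rule is pure half-max
   growth.
4. **Non-maximum suppression**: seeds are processed strongest-first; a seed
   inside an already-claimed ROI is suppressed, later floods cannot enter
   claimed pixels, and a candidate whose ROI contains a pixel brighter than
   its seed peak / `roi_growth_fraction` is suppressed as a flank artifact
   (its seed would lie outside that pixel's own half-max region). One
   release site yields one candidate.
5. **Refinement filters** (`filter_hotspots()`): rejection if (a) peak
   height varies across stimulation repeats by ≥ 500 %
   (100·(max−min)/min — the minimum denominator is the most permissive
   reading); (b) area < 1.64 μm², i.e. three 0.74-μm pixels, with an
   inclusive ≥ comparison so a 3-pixel ROI passes; (c) noise — peak SNR
   below `snr_min` = 3 versus the pre-stimulus MAD, trace maximum outside
   the evaluation window, or more than half of the non-DC spectral power
   above 1 Hz. The manual noise screening of the original workflow is thus
   replaced by three explicit, reproducible tests. Every rejection is
   logged with its reason, and accepted ∪ rejected always equals the
   candidate set.

Coordinates are 1-based (row, col) matrix indices; areas are always
|ROI|·pixel_size². `temporal_fwhm()` measures width at half of
(max − pre-stimulus median) with linear interpolation, flagging one-sided
transients instead of failing.

ROI construction from derivative-localized seeds with half-max growth is a
transparent reimplementation of the described analysis (derivative maxima,
FWHM/amplitude characterization), not a port of any released code; seeds
are localized on per-pixel traces rather than a mean-image trace, an
interpretation documented here deliberately.

## The synthetic generator

`simulate_movie()` renders: per site an isotropic 2-D Gaussian dopamine
concentration field (σ default from the sampled hotspot area; fields of
overlapping sites add in concentration space), a linear one-frame rise at
onset (sensor binding is effectively instantaneous at nanosecond scale)
followed by exponential clearance exp(−t/τ), Langmuir transduction
F = F₀·(1 + ΔF/F₀(c)), then Poisson shot noise and Gaussian read noise.
The sensor does not photobleach, so the pre-stimulus expectation is exactly
the baseline level. A seed fixes the whole movie bit-exactly, and the
caller's RNG state is left untouched.

**Group presets** carry the four groups' published statistics — measured
hotspot peak ΔF/F₀ (0.158 ± 0.084 control-early, 0.845 ± 0.364 PD-early,
0.513 ± 0.431 / 0.328 ± 0.312 late), per-FOV hotspot counts (45.0 ± 12.6,
55.8 ± 23.1 control; 17.0 ± 8.8, 16.3 ± 8.1 PD) and hotspot areas
(26 ± 21 and 32 ± 21 → 11 ± 13 μm²). The control-late area uses the early
value: the printed late-stage figure is internally inconsistent with the
accompanying "not statistically different" statement and is treated as a
typographical artifact. Peaks and areas are drawn from lognormals with
moments matched to mean ± sd (positive support and right skew, and —
unlike a truncated normal — an unbiased mean); counts from a rounded
normal truncated at zero. Counts are interpreted per field of view
regardless of geometry, since they are what the published per-FOV figures
report.

**Measured-domain calibration.** The preset peak values are *measurements*
(mean ΔF/F₀ over a detected half-max ROI at the sampled peak frame), so
the generator calibrates each site's amplitude such that that measurement,
under its own forward model, equals the sampled target: the target d is
converted to a center value via the half-max averaging factor
0.5/ln 2 ≈ 0.7213 (the mean of a Gaussian over its half-max disk), refined
against the actual pixel grid by a two-step fixed point, and finally
divided by the kinetics maximum over *frame times* — with onsets uniform
within 1 s of stimulation start, the 5-fps grid samples the transient on
average half a frame past its peak, which would otherwise cost ≈5 % of
amplitude. Ground truth records both the observable center-pixel peak
(`center_dff`) and the expected measured ROI peak (`peak_dff`).

**Site placement**: uniform positions with an edge margin, rejected until
every pair is separated by at least the sum of the two half-max radii plus
2 μm — per-FOV counts are counts of *resolved* hotspots, so the generator
plants configurations a detector can resolve.

**Chosen once, not in the data**: absolute clearance constants are not
published, only their 3.5-fold PD/control ratio; the defaults τ = 2 s
(control) and 7 s (PD) are conventions preserving that ratio. Noise
magnitudes are likewise unpublished; the defaults (baseline 5000 counts,
shot noise on, read-noise sd 10 counts) are typical InGaAs camera scales
giving per-pixel ΔF/F₀ noise of ≈1.4 %.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: dopamine diffusion (no reaction–diffusion
PDE; the Gaussian field is static in shape), quantal/vesicular release
variability, optics (no PSF), motion, uneven illumination or sensor
coating, and background cellular autofluorescence. Movies for testing are
also ≈20× denser in hotspots than a real field of view, because published
per-FOV counts are packed into a 128×128-pixel frame; residual tail
overlap at that density inflates detected areas by some tens of percent
(isolated-site areas are recovered within 15 %) and is the main remaining
bias on measured peaks (≈1–2 % low).

## Kinetics and statistics

`fit_clearance()` fits a·exp(−t/τ)+b from the trace peak by
Levenberg–Marquardt, initialized from a log-linear regression on the
offset-subtracted trace. The offset b absorbs residual baseline; τ is the
exponential constant alone. The fit reports `converged = FALSE` for
non-decaying input and for fits explaining <10 % of variance (pure noise),
rather than fabricating a constant. Noiseless recovery is exact to <0.1 %
across τ ∈ [0.5, 10] s; at SNR 10 the median bias is ≈1 % and the fitted
PD/control ratio concentrates at 3.5.

`size_categories()` bins areas at 9 and 36 μm² (squares of 3 and 6 μm;
boundaries inclusive into "middle"). `compare_groups()` runs the classical
pooled-variance two-tailed Student's t for two groups (Welch behind a
flag) or one-way ANOVA with Tukey's HSD for three or more, with star codes
at 0.05/0.01/0.005/0.001. Zero-variance equal-mean input returns p = 1
with a `degenerate` flag by convention.

## Numerical choices and degenerate inputs

* Seed ordering and all tie-breaks are lexicographic after score, so every
  stage is deterministic; no unordered-iteration leakage.
* The size threshold comparison is inclusive (≥ 1.64 μm²): three combined
  pixels pass.
* Movies shorter than the baseline window, windows without frames, spectra
  on mismatched grids, zero baseline intensity at a spectral peak, and
  sites outside the frame raise immediate typed errors; degenerate *data*
  (all-zero dose response, white-noise clearance traces) yield honest
  failure reports instead.
* `nlsLM` runs with default convergence control: machine-tight tolerances
  make its post-fit model construction abort on zero-residual (noiseless)
  data.

## Problem sizes used by the tests

The suite validates at scales chosen for completeness per CPU-minute:
preset recovery on 128×128×150-frame movies (3 per run), preset sampling
fidelity over 50 seeded site draws per group, detection recall/precision
on 10 planted sites per movie over 3 seeds, clearance Monte-Carlo over
25–200 seeds, and brute-force oracle equivalence on 16×16×50 movies. The
acceptance script (`scripts/acceptance.R`) re-derives the calibrated
100-μM response, the clearance-τ ratio and the control-early per-FOV
hotspot count from scratch at those same scales.

## Known limitations

* Hotspot areas measured on densely packed synthetic FOVs run above the
  generative half-max truth (overlapping tails); area-dependent statistics
  on such movies should be read with that in mind.
* The detector assumes a stable baseline (the sensor does not bleach); it
  has no motion correction or flat-fielding, by design.
* Subpixel localization, hotspot tracking across movies, and deconvolution
  of release trains are out of scope.
* The variation filter needs per-repeat traces; with a single stimulation
  repeat it passes trivially.
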