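---
title: "Functional ultrasound power Doppler and activation mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional ultrasound power Doppler and activation mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fusact)
```

# Overview

`fusact` implements the analysis chain of functional ultrasound (fUS)
neuroimaging for block-design stimulation experiments:

1. **Doppler core** — per-angle beamformed complex frames are coherently
   compounded, temporally averaged, cut into non-overlapping slow-time
   blocks, clutter-filtered by singular value decomposition (SVD) of each
   block's Casorati matrix, and reduced to one power Doppler image per
   block.
2. **Preprocessing** — subpixel motion correction of the Doppler series,
   spatial Gaussian smoothing, voxelwise normalization to percent change
   against the pre-stimulus baseline, and a centered temporal moving
   average.
3. **Activation mapping** — a voxelwise general linear model (GLM) against
   the stimulus boxcar convolved with a gamma hemodynamic response function
   (HRF), thresholded with Benjamini–Hochberg false discovery rate (FDR)
   control.
4. **ROI statistics** — time courses, baseline z-scores, and
   stimulation-versus-rest t-tests for reactive and nonreactive regions of
   interest.
5. **Quality metrics** — contrast-to-noise ratio (CNR) and full width at
   half maximum (FWHM) of vessel profiles.
6. **Synthetic phantom** — a seeded generator of ultrafast-Doppler frame
   sequences with known ground truth, so every stage above is testable
   without patient data.

No clinical dataset ships with the package; the phantom generator defines
the study conditions that the test suite and the acceptance script measure.

# The Doppler core

## Acquisition arithmetic

The default acquisition mirrors a 7.8-MHz linear array driven with seven
plane-wave transmit angles (−6° … 6° in 2° steps) and triple temporal
averaging at a 500 Hz compounded frame rate, so the pulse repetition
frequency is the product 500 × 7 × 3 = 10.5 kHz. One power Doppler image is
formed from each non-overlapping block of 250 compounded frames, giving the
2 Hz Doppler frame rate (`doppler_movie()`); blocks are aligned to the
acquisition start and timestamps are block centers.

## SVD clutter filtering

Each block is rearranged into a Casorati matrix (pixels × slow time;
flattening order is documented as `p = (z − 1) n_x + x` and round-trip
tested). Tissue clutter is high-amplitude and temporally coherent, so it
concentrates in the lowest-order (largest) singular components. The filter
removes the `k = floor(f · n_t)` largest components with `f = 0.13` by
default — 32 of 250 components — and reconstructs the blood signal from the
remainder. Design choices, where the convention was genuinely open:

* the threshold is interpreted as a **component-count fraction** (rank
  cutoff), the standard practice in ultrafast Doppler, not an energy
  fraction;
* rounding uses `floor` (conservative tissue removal);
* the fraction is applied **per block** (configurable via
  `svd_fraction`);
* no additional spectral wall filter is applied.

Power Doppler is the per-pixel temporal mean of the squared magnitude of
the filtered block, so it is proportional to moving-blood volume; all
singular values and the removed count are reported alongside the images.

# Preprocessing

The order is fixed and logged: motion correction → spatial smoothing →
normalization → temporal smoothing.

* **Motion correction** registers each Doppler frame to a reference frame
  by subpixel translation (cross-correlation peak with parabolic
  interpolation, bilinear resampling). This is a deliberate simplification
  of fully nonrigid registration: block-level translation is what the
  2 Hz series can constrain, and `correct_motion()` accepts externally
  computed displacement fields for anything richer. Displacements are
  logged per frame.
* **Spatial smoothing** is a 2-D Gaussian with σ = 1 **pixel** (the unit
  is a deliberate choice; the filter acts on image arrays) and reflective
  boundaries.
* **Normalization** defaults to percent change,
  `100 (x − μ_ref) / μ_ref`, against the 20-s pre-stimulus baseline,
  because responses are conventionally reported as percent CBV change; a
  `demean` mode (idempotent) is also provided. Voxels with non-positive
  reference means are flagged invalid and excluded downstream.
* **Temporal smoothing** is a centered 5-point moving average with
  shrinking windows at the edges.

# Activation mapping

## The HRF and design matrix

The hemodynamic response is the delayed gamma

$$h(t) = \left(\frac{t-\delta}{\tau}\right)^{n-1}
         e^{-(t-\delta)/\tau}, \quad t \ge \delta,$$

with defaults τ = 0.7 s, δ = 1.5 s, n = 3, peak-normalized to 1; its
analytic maximum is at δ + (n − 1)τ = 2.9 s. Among the gamma
parameterizations in circulation this form maps the three named parameters
directly and is isolated in one function (`gamma_hrf()`) should a user
need a different convention. The task regressor is the stimulus boxcar
convolved with this kernel, sampled at block centers and peak-normalized,
so the fitted slope is the peak response in percent-change units; the
design adds an intercept and (optionally) a linear drift, which is off by
default because no confound regressors are part of the standard chain.

## GLM, serial correlation, and FDR

`fit_glm()` is ordinary least squares per voxel with
`t = β_task / se(β_task)`. One correction matters in practice: the 5-point
moving average introduces strong serial correlation, and naive OLS t-scores
on smoothed null data have a standard deviation near 3 rather than 1. Since
the smoothing filter is known exactly, the package applies the standard
known-filter correction: the regressors are smoothed with the same matrix
`S` (the model is `y = SXβ + Sε`), the slope variance uses the induced
covariance `V = SS'`, and a Satterthwaite effective degrees of freedom
`tr(RV)²/tr(RVRV)` replaces `n − k`. With this correction the null
p-values are uniform (verified by Kolmogorov–Smirnov tests in the suite)
and FDR control holds.

Voxelwise significance is declared at q < 10⁻³ after Benjamini–Hochberg
adjustment (the FDR method is recorded in the map's provenance; the count
of voxels passing the same threshold uncorrected is reported alongside,
since a reader may want either convention). Tests are two-sided by
default, with a one-sided "increases only" option.

# ROI statistics

ROIs are ~2 mm × 2 mm rectangles (pixel bounds derived from the pixel
spacings, half-open). `select_rois()` restricts candidate windows to
well-vascularized locations (window-mean power Doppler at or above the
70th percentile), then maximizes the window-mean t-score for reactive ROIs
and minimizes the mean |t| for nonreactive ones, with deterministic
(row, column) tie-breaking — t-scores stand in for "correlation values"
because the GLM t is monotone in the regressor correlation.

`stim_response_stats()` compares blocks inside the hemodynamically lagged
stimulation windows `[onset + lag, onset + duration + lag)` — the default
lag is the HRF peak time, 2.9 s, and is configurable because response
windowing conventions differ — against rest. Rest is either all blocks
outside the stimulus/transition windows (default) or the pre-stimulus
baseline only; both are provided because published analyses are often
ambiguous on this point. The test is Welch's two-sided t-test by default
(Student's pooled test optional, since "t test" alone does not pin the
variant), and results carry significance flags at both the 0.001 and 10⁻⁵
thresholds, the two conventions in circulation for ROI-level significance.
Baseline z-scores use the sample (n − 1) standard deviation of the
pre-stimulus window.

# Quality metrics

CNR is `20 log10((μ_s − μ_b)/σ_b)` between a signal and a background
region of the linear-power Doppler image; because no universal convention
exists, the definition (`amplitude` 20-log or `power` 10-log) is always
recorded next to the value and bounds are only ever checked against the
recorded definition. FWHM of a profile is measured after subtracting the
profile's edge median, with linear interpolation of the half-maximum
crossings; sub-sample widths are flagged as resolution-floor results.

# The synthetic phantom

## Signal model

The generator emulates, at the compounded 500 Hz slow-time clock:

* **tissue clutter**: a smooth positive amplitude map (zeroed inside
  vessel lumina, since a lumen carries blood rather than tissue) times a
  rank-≤ 3 temporal modulation (constant plus two smooth seeded basis
  functions, ±2%), with spatially smooth speckle phase at the ~1.5-pixel
  speckle-cell scale;
* **blood**: each vessel pixel rotates at its Doppler frequency
  `f_d = 2 v f_c / c`, with laminar (parabolic) velocity profiles across
  the lumen, 8% intravoxel velocity jitter, and a per-pixel complex AR(1)
  speckle process whose correlation time is the blood transit time through
  the speckle cell (capped at 8 ms). Speckle decorrelation is essential,
  not cosmetic: without it the blood occupies only
  (occupied bandwidth × block duration) ≈ 30 temporal dimensions and the
  fixed 32-component cutoff would remove most of the blood signal, which
  is not how ultrafast Doppler behaves on real vasculature;
* **activation**: on activated pixels the blood amplitude scales as
  `sqrt(1 + ΔCBV(t))` with
  `ΔCBV(t) = effect_size × (boxcar ⊛ HRF, peak-normalized)`, so power
  Doppler scales exactly as `1 + ΔCBV(t)` and recovery tests are exact;
* **noise**: additive complex white receiver noise;
* **motion**: a smooth-nonrigid (or rigid) displacement field with ≤ 0.5 px
  default amplitude and a ~10 s correlation time, applied to the
  tissue/clutter field before noise is added. Motion is not applied to the
  blood speckle or the receiver noise: envelope-domain resampling of
  spatially white fields attenuates their power by up to 4× depending on
  the fractional displacement, a resampling artifact with no physical
  counterpart (receiver noise enters after tissue motion, and flowing
  blood speckle regenerates within milliseconds, so sub-pixel lumen
  displacement has no observable effect on it).

Default amplitudes (tissue 200, blood 3.5, noise 1) put clutter ≈ 35 dB
above blood and blood ≈ 11 dB above the noise floor — the regime in which SVD
clutter filtering is both necessary and effective. Default peak velocities
(10–19 mm/s) stay below the 500-Hz slow-time Nyquist bound
`v < c f_frame / (4 f_c) ≈ 24.7 mm/s`, which the generator enforces; this
is the binding aliasing constraint once the Doppler phase clock is fixed
at the compounded rate.

The default stimulation protocol is a 20-s baseline followed by three 5-s
stimuli separated by 20-s rests (onsets 20, 45, 70 s; 95 s total; 190
Doppler frames at 2 Hz).

`simulate_angle_frames()` expands the same signal to the per-angle,
pre-averaging stream (each compounded frame replicated
`factor × n_angles` times with independent raw noise scaled so that
compounding recovers the compounded-level statistics). The full-scale
per-angle stream for a 95-s protocol is ~10⁹ complex samples, so the
compounded-level generator (`simulate_compound_frames()`) is the one used
for long simulations; the per-angle path is exercised on small
configurations where the two are verified to agree after compounding and
averaging.

## What the phantom does and does not emulate

It reproduces the features the pipeline's behavior depends on: clutter ≫
blood ≫ noise amplitude ordering, low-rank tissue dynamics, blood spread
over many singular components, stimulus-locked multiplicative CBV changes,
slow nonrigid motion, receiver noise. It does **not** model speckle
physics from first principles, raw-channel data or beamforming,
attenuation/penetration differences between transducer frequencies,
cardiac/respiratory pulsatility, or fast periodic motion. Passing tests
therefore demonstrate the correctness and calibration of the analysis
chain under realistic amplitude/bandwidth regimes — not clinical
performance on patient data. In particular, within-block motion of
high-amplitude clutter is only benign here because the default motion is
slow; fast motion would defeat block-level correction in this pipeline, a
known limitation stated above.

## Problem sizes in the test suite

The suite runs the full 95-s protocol once on a 32 × 32 grid (190 blocks
of 250 frames) and reuses that run across test files; shorter protocols
and 16–64 pixel grids cover the remaining properties. The acceptance
script averages 10 seeded phantoms for the CNR bound (64 × 64, one block
window) and runs 10 full-protocol phantoms (32 × 32) for the
reactive-ROI significance bound. These sizes were chosen so the whole
suite completes comfortably on a single CPU while every probabilistic
assertion retains enough samples to be stable.

# Numerical choices and degenerate inputs

* Casorati flattening order and its inverse are round-trip tested;
  `svd_fraction = 0` is the exact identity.
* Spatial smoothing uses reflective boundaries; temporal smoothing
  shrinks its window at the edges; both are identity at their neutral
  parameters (σ = 0, window = 1).
* Ties in ROI selection break by (row, column) order; an all-zero t-map
  falls back to vascular-intensity ordering with a warning.
* All-constant frames cannot be registered; they keep the identity
  transform with a warning and an `NA` in the displacement log.
* Voxels with non-positive baseline means are `NaN` throughout and are
  excluded from GLM maps and ROI means (with counts logged).
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; equal seeds give bit-identical output.

# Reproducing a full run

```{r}
cfg <- list(seed = 7, out_dir = "fus_run",
            scene = list(grid_shape = c(32, 32), n_vessels = 2,
                         effect_size = 0.10))
report <- run_pipeline(cfg)
report$roi_report$reactive_1$p_value
```

`run_pipeline()` writes the Doppler series (NIfTI + JSON sidecar),
singular-value spectra, displacement logs, activation maps, ROI report,
quality metrics and a provenance record; identical configurations and
seeds reproduce every output byte-for-byte (timestamps live only in the
provenance file).
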