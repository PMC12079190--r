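# fusact

Functional ultrasound (fUS) neuroimaging infers neural activity from
stimulus-locked changes in cerebral blood volume, imaged as ultrafast
power Doppler at frame rates of a few hertz. `fusact` is an R
implementation of the full analysis chain for block-design fUS
experiments — from beamformed complex frame stacks to FDR-thresholded
activation maps and ROI statistics — together with a seeded synthetic
phantom generator that emulates an auditory-stimulation experiment, so
the whole pipeline can be developed, tested and calibrated without
patient data. It is aimed at researchers building or validating fUS
processing chains (e.g. for bedside monitoring studies) who need a
reference implementation with known ground truth.

## The pipeline

1. **Doppler core.** Per-angle complex frames are coherently compounded
   over the transmit angles and temporally averaged (default: 7 angles,
   triple averaging, 500 Hz compounded rate, PRF = 10.5 kHz). Each
   non-overlapping block of 250 frames is rearranged into a Casorati
   matrix `C` (pixels × slow time) and clutter-filtered by SVD: with
   `C = U Σ Vᴴ`, the `k = ⌊0.13 · n_t⌋` largest components (the tissue
   subspace) are removed and the power Doppler image is the temporal mean
   of `|C_filtered|²` per pixel — one image per block, i.e. a 2 Hz series.
2. **Preprocessing.** Subpixel translation motion correction (phase of the
   cross-correlation peak), 2-D Gaussian smoothing (σ = 1 px), voxelwise
   percent-change normalization against the 20-s pre-stimulus baseline,
   and a 5-point temporal moving average.
3. **Activation mapping.** Voxelwise GLM of the normalized series on the
   stimulus boxcar convolved with a gamma HRF
   `h(t) = ((t−δ)/τ)^{n−1} e^{−(t−δ)/τ}` (τ = 0.7 s, δ = 1.5 s, n = 3;
   peak at 2.9 s), with the moving-average serial correlation folded into
   the t-statistics (effective degrees of freedom), and Benjamini–Hochberg
   FDR thresholding at q < 10⁻³.
4. **ROI statistics.** Reactive/nonreactive ~2 mm × 2 mm ROIs selected
   from the t-map on well-vascularized pixels; ROI time courses, baseline
   z-scores, and Welch t-tests of the lag-shifted stimulation windows
   against rest.
5. **Quality metrics.** Contrast-to-noise ratio in dB (definition
   recorded with the value) and FWHM of vessel profiles in µm.

The methods vignette (`vignettes/fus-activation-mapping.Rmd`) documents
the models, parameter choices and the phantom's signal model in detail.

## Worked example

Simulate the default auditory experiment — a 20-s baseline and three 5-s
stimuli separated by 20-s rests — on a 32 × 32 phantom with two vessels
and a 10% CBV increase on the first vessel, then run the full analysis:

```r
library(fusact)

acq      <- acq_params()                 # 7.8 MHz, 7 angles, 500 Hz, 250-frame blocks
protocol <- default_protocol()           # onsets 20/45/70 s, 95 s total
scene    <- make_phantom(c(32, 32), n_vessels = 2, effect_size = 0.10, seed = 1)

frames <- simulate_compound_frames(scene, protocol, acq, seed = 2)
pd     <- doppler_movie(frames, svd_fraction = 0.13)
pd
#> Power Doppler series: 190 frames of 32 x 32 at 2 Hz (SVD fraction 0.13, 250 frames/block)

act <- activation_pipeline(pd, protocol)            # preprocess + GLM + FDR
act$threshold$n_corrected                           # voxels with q < 1e-3
#> [1] 334

rois <- select_rois(act, apply(pd$images, c(2, 3), mean))
tc   <- extract_roi_timeseries(attr(act, "series"), rois$reactive[[1]])
stim_response_stats(tc, protocol, pd$block_rate)
#> ROI response: mean difference = 2.79%, t = 17.1 (df 33.3), P = 4.96e-18 (welch, pooled rest)
```

The activation map recovers the injected effect (334 significant voxels,
concentrated on the activated vessel and its smoothing halo), and the
reactive ROI shows a clearly significant stimulation response: the mean
difference is the average percent CBV change of the ROI during the
hemodynamically lagged stimulation windows relative to rest — smaller
than the injected 10% because the 2 mm ROI averages activated vessel
pixels with surrounding tissue — and `P` is the Welch t-test p-value,
far below the 0.001 significance convention. (On this deliberately small
6.4 mm field of view the 2 mm "nonreactive" control ROI cannot fully
escape the activated vessel's smoothing halo and still picks up a 1.6%
response; on larger grids it is null, as the package's test suite checks
at the time-course level.) Image quality on the same phantom:

```r
quality_report(pd, scene_vessel_mask(scene), scene_background_mask(scene))$cnr_db
#> [1] 56.2
```

`run_pipeline(list(seed = 7, out_dir = "fus_run", scene = list(grid_shape =
c(32, 32))))` executes the same
chain from a single (validated) configuration and writes every
intermediate — Doppler series as NIfTI with JSON sidecars,
singular-value spectra and displacement logs as CSV, activation volumes,
and JSON reports — reproducibly for a given seed.

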