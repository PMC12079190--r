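# Readers/writers (NIfTI + JSON sidecar), run configuration and the
# end-to-end pipeline orchestrator.

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

acq_to_list <- function(acq) {
  unclass(acq)
}

acq_from_list <- function(lst) {
  acq_params(center_frequency = lst$center_frequency,
             compound_frame_rate = lst$compound_frame_rate,
             angles_deg = lst$angles_deg,
             temporal_averaging_factor = lst$temporal_averaging_factor,
             frames_per_block = lst$frames_per_block,
             speed_of_sound = lst$speed_of_sound,
             pixel_spacing_z = lst$pixel_spacing_z,
             pixel_spacing_x = lst$pixel_spacing_x)
}

#' Write / read complex frame sequences
#'
#' Frame sequences are stored as 5-D NIfTI volumes
#' `(z, x, angle, time, real/imag)` (`angle` axis of length 1 for
#' compounded sequences) with a JSON sidecar (same basename, `.json`)
#' carrying the acquisition metadata and the sequence kind. `read_frames()`
#' validates the sidecar against the array (angle count, finiteness) and
#' returns the matching sequence class.
#'
#' @param seq A `fus_angle_seq` or `fus_compound_seq`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns the sequence object.
#' @export
write_frames <- function(seq, path) {
  is_angle <- inherits(seq, "fus_angle_seq")
  if (!is_angle && !inherits(seq, "fus_compound_seq"))
    stopf("expected a fus_angle_seq or fus_compound_seq")
  fr <- seq$frames
  if (!is_angle) {
    d <- dim(fr)
    dim(fr) <- c(d[1], 1L, d[2], d[3])  # insert singleton angle axis
  }
  a <- aperm(fr, c(3, 4, 2, 1))  # (z, x, angle, time)
  arr <- array(0, dim = c(dim(a), 2L))
  arr[, , , , 1] <- Re(a)
  arr[, , , , 2] <- Im(a)
  RNifti::writeNifti(arr, path)
  meta <- list(kind = if (is_angle) "angle" else "compound",
               acq = acq_to_list(seq$acq))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing JSON sidecar: %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  acq <- acq_from_list(meta$acq)
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) != 5L || d[5] != 2L)
    stopf("expected a 5-D (z, x, angle, time, re/im) volume")
  if (any(!is.finite(arr))) stopf("frame data contain non-finite values")
  cx <- arr[, , , , 1] + 1i * arr[, , , , 2]
  dim(cx) <- d[1:4]
  fr <- aperm(cx, c(4, 3, 1, 2))  # (time, angle, z, x)
  if (identical(meta$kind, "angle")) {
    if (dim(fr)[2] != length(acq$angles_deg))
      stopf("sidecar lists %d angles but the array has %d",
            length(acq$angles_deg), dim(fr)[2])
    structure(list(frames = fr, acq = acq), class = "fus_angle_seq")
  } else {
    if (dim(fr)[2] != 1L)
      stopf("compounded sequence must have a singleton angle axis")
    fr2 <- fr[, 1, , ]
    dim(fr2) <- dim(fr)[c(1, 3, 4)]
    structure(list(frames = fr2, acq = acq), class = "fus_compound_seq")
  }
}

#' Write / read a power Doppler series
#'
#' Stored as a 4-D NIfTI volume `(z, x, 1, block_time)` plus a JSON sidecar
#' with block rate, timestamps, pixel spacings and filter provenance.
#'
#' @param pd A `fus_pd_series`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_pd_series()` returns `path` invisibly; `read_pd_series()`
#'   the series.
#' @export
write_pd_series <- function(pd, path) {
  stopifnot(inherits(pd, "fus_pd_series"))
  a <- aperm(pd$images, c(2, 3, 1))
  d <- dim(a)
  dim(a) <- c(d[1], d[2], 1L, d[3])
  RNifti::writeNifti(a, path)
  meta <- list(block_rate = pd$block_rate,
               block_timestamps = pd$block_timestamps,
               pixel_spacing_z = pd$pixel_spacing_z,
               pixel_spacing_x = pd$pixel_spacing_x,
               provenance = pd$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pd_series
#' @export
read_pd_series <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing JSON sidecar: %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) != 4L) stopf("expected a 4-D (z, x, 1, time) volume")
  images <- aperm(arr[, , 1, , drop = FALSE][, , 1, ], c(3, 1, 2))
  structure(list(
    images = images,
    block_rate = meta$block_rate,
    block_timestamps = meta$block_timestamps,
    pixel_spacing_z = meta$pixel_spacing_z,
    pixel_spacing_x = meta$pixel_spacing_x,
    singular_values = NULL,
    provenance = meta$provenance
  ), class = "fus_pd_series")
}

# Allowed configuration schema (defaults). Unknown keys anywhere are
# rejected before any computation.
config_schema <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    scene = list(grid_shape = c(64L, 64L), n_vessels = 2L,
                 effect_size = 0.10, tissue_amplitude = 200,
                 blood_amplitude = 3.5, noise_sigma = 1,
                 vessel_width_px = 4, flow_profile = "parabolic"),
    protocol = list(baseline_duration = 20, onsets = c(20, 45, 70),
                    durations = c(5, 5, 5), total_duration = 95),
    acq = acq_to_list(acq_params())[setdiff(names(acq_to_list(acq_params())), "prf")],
    hrf = list(tau = 0.7, delta = 1.5, n = 3),
    motion = list(kind = "smooth-nonrigid", max_displacement_px = 0.5,
                  temporal_scale_s = 10, spatial_scale_px = 8),
    doppler = list(svd_fraction = 0.13),
    preprocess = list(motion_correct = TRUE, sigma = 1,
                      mode = "percent_change", window = 5L),
    activation = list(q = 1e-3, alternative = "two.sided"),
    roi = list(roi_size_m = 2e-3, n_each = 1L, vascular_quantile = 0.7,
               rest_mode = "pooled")
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" under ", path) else "",
          paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, k, "/"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML or JSON file (by extension) or a plain nested list, and
#' merges it over the package defaults. Unknown keys are rejected before
#' any computation; `seed` and `out_dir` are mandatory at run time.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a nested list.
#' @return Validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  merge_config(config_schema(), config)
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate -> Doppler -> preprocess -> activation -> ROI ->
#' quality metrics from one configuration and writes every intermediate and
#' a provenance record to `out_dir`: `pd.nii.gz` (+ sidecar),
#' `singular_values.csv`, `displacements.csv`, `activation.nii.gz`
#' (beta / t / p / q / mask volumes), `roi_report.json`, `quality.json`
#' and `provenance.json`. Deterministic given `seed` (timestamps live only
#' in the provenance record).
#'
#' @param config See [read_run_config()]; must provide `out_dir`.
#' @return Invisibly, a list with the in-memory results (`pd`, `activation`,
#'   `roi_report`, `quality`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out_dir)) stopf("config must set out_dir")
  if (is.null(cfg$seed)) stopf("config must set seed")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- acq_from_list(cfg$acq)
  protocol <- stimulus_protocol(cfg$protocol$baseline_duration,
                                cfg$protocol$onsets, cfg$protocol$durations,
                                cfg$protocol$total_duration)
  hrf <- hrf_params(cfg$hrf$tau, cfg$hrf$delta, cfg$hrf$n)
  motion <- motion_model(cfg$motion$kind, cfg$motion$max_displacement_px,
                         cfg$motion$temporal_scale_s,
                         cfg$motion$spatial_scale_px)
  scene <- make_phantom(grid_shape = cfg$scene$grid_shape,
                        n_vessels = cfg$scene$n_vessels,
                        effect_size = cfg$scene$effect_size,
                        seed = cfg$seed, acq = acq,
                        tissue_amplitude = cfg$scene$tissue_amplitude,
                        blood_amplitude = cfg$scene$blood_amplitude,
                        noise_sigma = cfg$scene$noise_sigma,
                        vessel_width_px = cfg$scene$vessel_width_px,
                        flow_profile = cfg$scene$flow_profile)
  seq <- simulate_compound_frames(scene, protocol, acq, hrf, motion,
                                  seed = cfg$seed + 1L)
  pd <- doppler_movie(seq, svd_fraction = cfg$doppler$svd_fraction)
  write_pd_series(pd, file.path(cfg$out_dir, "pd.nii.gz"))
  utils::write.csv(as.data.frame(pd$singular_values),
                   file.path(cfg$out_dir, "singular_values.csv"),
                   row.names = FALSE)

  act <- activation_pipeline(pd, protocol, hrf, q = cfg$activation$q,
                             alternative = cfg$activation$alternative,
                             motion_correct = cfg$preprocess$motion_correct,
                             sigma = cfg$preprocess$sigma,
                             mode = cfg$preprocess$mode,
                             window = cfg$preprocess$window)
  ns <- attr(act, "series")
  if (!is.null(ns$motion_log))
    utils::write.csv(ns$motion_log,
                     file.path(cfg$out_dir, "displacements.csv"),
                     row.names = FALSE)
  act_arr <- array(0, dim = c(dim(act$t_score), 1L, 5L))
  act_arr[, , 1, 1] <- act$beta
  act_arr[, , 1, 2] <- act$t_score
  act_arr[, , 1, 3] <- act$p_value
  act_arr[, , 1, 4] <- act$q_value
  act_arr[, , 1, 5] <- act$mask
  RNifti::writeNifti(act_arr, file.path(cfg$out_dir, "activation.nii.gz"))

  pd_mean <- apply(pd$images, c(2, 3), mean)
  rois <- select_rois(act, pd_mean, roi_size_m = cfg$roi$roi_size_m,
                      n_each = cfg$roi$n_each,
                      vascular_quantile = cfg$roi$vascular_quantile,
                      spacing_z = acq$pixel_spacing_z,
                      spacing_x = acq$pixel_spacing_x)
  roi_report <- list()
  for (cls in c("reactive", "nonreactive")) {
    for (i in seq_along(rois[[cls]])) {
      roi <- rois[[cls]][[i]]
      tc <- extract_roi_timeseries(ns, roi)
      st <- stim_response_stats(tc, protocol, pd$block_rate, hrf = hrf,
                                rest_mode = cfg$roi$rest_mode)
      roi_report[[sprintf("%s_%d", cls, i)]] <- list(
        label = cls,
        rows = roi$rows, cols = roi$cols,
        mean_diff_percent = st$mean_diff_percent,
        t_statistic = st$t_statistic,
        p_value = st$p_value,
        df = st$df,
        per_stimulus_means = st$per_stimulus_means,
        n_stim = st$n_stim, n_rest = st$n_pre,
        significant_p001 = st$significant_p001,
        significant_p1e5 = st$significant_p1e5)
    }
  }
  jsonlite::write_json(roi_report,
                       file.path(cfg$out_dir, "roi_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  quality <- cnr(pd_mean, scene_vessel_mask(scene),
                 scene_background_mask(scene))
  quality$n_active_voxels_fdr <- act$threshold$n_corrected
  quality$n_active_voxels_uncorrected <- act$threshold$n_uncorrected
  jsonlite::write_json(quality, file.path(cfg$out_dir, "quality.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  prov <- list(package_version = as.character(utils::packageVersion("fusact")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = cfg[setdiff(names(cfg), "out_dir")])
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scene = scene, pd = pd, activation = act,
                 rois = rois, roi_report = roi_report, quality = quality))
}
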