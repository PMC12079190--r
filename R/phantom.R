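# Synthetic ultrafast-Doppler phantom: ground-truth scenes and seeded
# simulation of beamformed complex frame sequences emulating a block-design
# auditory fUS experiment.

#' Construct a phantom scene
#'
#' Low-level constructor for a ground-truth scene: a tissue amplitude map,
#' a list of vessel segments and an activation mask. Most users should call
#' [make_phantom()], which draws a randomized scene from a seed.
#'
#' Each vessel segment is a list with elements `mask` (logical nz x nx),
#' `axial_velocity` (signed peak axial velocity, m/s), `blood_amplitude`
#' (scalar) and optionally `velocity_map` (numeric nz x nx per-pixel axial
#' velocities; defaults to `axial_velocity` everywhere on the mask, i.e.
#' plug flow).
#'
#' @param grid_shape Integer vector `c(nz, nx)`, both >= 16.
#' @param tissue_amplitude Nonnegative numeric nz x nx map of tissue
#'   (clutter) echo amplitude.
#' @param vessel_segments List of vessel segments (see Details).
#' @param activation_mask Logical nz x nx mask of pixels whose blood signal
#'   carries the stimulus-locked CBV increase; must be a subset of the union
#'   of vessel masks.
#' @param effect_size Fractional peak CBV increase on activated pixels
#'   (e.g. 0.10 for a 10% increase); >= 0.
#' @param noise_sigma Standard deviation of the additive complex white noise
#'   at the compounded-frame level (E|n|^2 = noise_sigma^2).
#' @return Object of class `fus_phantom_scene`.
#' @export
phantom_scene <- function(grid_shape, tissue_amplitude, vessel_segments,
                          activation_mask, effect_size, noise_sigma) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 16L))
    stopf("grid_shape must be c(nz, nx) with both >= 16")
  dm <- function(x) identical(dim(x), grid_shape)
  if (!dm(tissue_amplitude) || any(tissue_amplitude < 0))
    stopf("tissue_amplitude must be a nonnegative %d x %d map",
          grid_shape[1], grid_shape[2])
  if (!dm(activation_mask) || !is.logical(activation_mask))
    stopf("activation_mask must be a logical map conforming to grid_shape")
  for (v in vessel_segments) {
    if (!dm(v$mask) || !is.logical(v$mask))
      stopf("each vessel mask must be a logical map conforming to grid_shape")
    if (!is.numeric(v$axial_velocity) || !is.numeric(v$blood_amplitude) ||
        v$blood_amplitude < 0)
      stopf("vessel segments need axial_velocity and blood_amplitude >= 0")
    if (!is.null(v$velocity_map) && !dm(v$velocity_map))
      stopf("velocity_map must conform to grid_shape")
  }
  vu <- vessel_union(vessel_segments, grid_shape)
  if (any(activation_mask & !vu))
    stopf("activation_mask must be a subset of the union of vessel masks")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  structure(list(
    grid_shape = grid_shape,
    tissue_amplitude = tissue_amplitude,
    vessel_segments = vessel_segments,
    activation_mask = activation_mask,
    effect_size = effect_size,
    noise_sigma = noise_sigma
  ), class = "fus_phantom_scene")
}

#' @export
print.fus_phantom_scene <- function(x, ...) {
  cat(sprintf(
    "Phantom scene %d x %d: %d vessel(s), %d activated px, effect %.3g, noise sigma %.3g\n",
    x$grid_shape[1], x$grid_shape[2], length(x$vessel_segments),
    sum(x$activation_mask), x$effect_size, x$noise_sigma))
  invisible(x)
}

# Union of vessel masks (all-FALSE map when there are no vessels).
vessel_union <- function(segments, grid_shape) {
  m <- matrix(FALSE, grid_shape[1], grid_shape[2])
  for (v in segments) m <- m | v$mask
  m
}

#' Ground-truth masks of a phantom scene
#'
#' `scene_vessel_mask()` returns the union of all vessel masks;
#' `scene_background_mask()` returns tissue-only pixels at least `margin`
#' pixels away (Chebyshev distance) from any vessel.
#'
#' @param scene A [phantom_scene()].
#' @param margin Dilation radius in pixels (default 1).
#' @return Logical nz x nx matrix.
#' @export
scene_vessel_mask <- function(scene) {
  vessel_union(scene$vessel_segments, scene$grid_shape)
}

#' @rdname scene_vessel_mask
#' @export
scene_background_mask <- function(scene, margin = 1L) {
  m <- scene_vessel_mask(scene)
  d <- m
  for (dz in -margin:margin) for (dx in -margin:margin) {
    if (dz == 0 && dx == 0) next
    s <- matrix(FALSE, nrow(m), ncol(m))
    zs <- seq_len(nrow(m)) - dz
    xs <- seq_len(ncol(m)) - dx
    ok_z <- zs >= 1 & zs <= nrow(m)
    ok_x <- xs >= 1 & xs <= ncol(m)
    s[ok_z, ok_x] <- m[zs[ok_z], xs[ok_x]]
    d <- d | s
  }
  !d
}

#' Generate a randomized phantom scene
#'
#' Draws a seeded ground-truth scene: a smooth positive tissue-amplitude
#' field (zeroed inside vessel lumina), `n_vessels` tube-shaped vessels with
#' laminar (parabolic) or plug axial-velocity profiles, and an activation
#' mask covering the first vessel when `effect_size > 0`. Identical
#' arguments and seed reproduce the scene exactly.
#'
#' Default amplitudes put tissue clutter ~35 dB above blood and blood ~11 dB
#' above the noise floor, the regime in which SVD clutter filtering is both
#' necessary and effective.
#'
#' @param grid_shape `c(nz, nx)`, both >= 16 (default 64 x 64).
#' @param n_vessels Number of vessels (>= 0, default 2).
#' @param effect_size Fractional peak CBV increase on activated pixels
#'   (default 0.10).
#' @param seed Integer seed.
#' @param acq [acq_params()] used only to enforce the slow-time aliasing
#'   bound on vessel velocities.
#' @param tissue_amplitude Scalar tissue echo amplitude (default 200).
#' @param blood_amplitude Scalar blood echo amplitude (default 3.5).
#' @param noise_sigma Complex noise standard deviation (default 1).
#' @param vessel_width_px Vessel lumen width in pixels (default 4, i.e.
#'   ~0.8 mm at the default spacing — the medium cortical vessels these
#'   probes resolve).
#' @param velocity_range Range (m/s) from which peak axial speeds are drawn
#'   (default 10-19 mm/s, medium cortical vessels; the upper end stays
#'   below the slow-time aliasing bound).
#' @param flow_profile `"parabolic"` (laminar; spreads Doppler frequencies
#'   across the lumen so blood energy is distributed over many singular
#'   components) or `"plug"` (uniform velocity; used for analytic
#'   single-frequency checks).
#' @param velocity_jitter Relative per-pixel random velocity perturbation
#'   (default 0.08, an intravoxel velocity spread); decorrelates pixels
#'   that share a velocity.
#' @param speckle Logical (default TRUE): modulate every vessel pixel by an
#'   independent complex AR(1) speckle process whose correlation time is
#'   the blood transit time through the ~1/3-pixel speckle cell (capped at
#'   8 ms). This is what distributes blood energy across many singular
#'   components in real ultrafast Doppler; disable it only for analytic
#'   single-tone checks.
#' @return A [phantom_scene()].
#' @export
make_phantom <- function(grid_shape = c(64L, 64L), n_vessels = 2L,
                         effect_size = 0.10, seed = 1L,
                         acq = acq_params(),
                         tissue_amplitude = 200, blood_amplitude = 3.5,
                         noise_sigma = 1, vessel_width_px = 4,
                         velocity_range = c(0.010, 0.019),
                         flow_profile = c("parabolic", "plug"),
                         velocity_jitter = 0.08, speckle = TRUE) {
  flow_profile <- match.arg(flow_profile)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 16L))
    stopf("grid_shape must be c(nz, nx) with both >= 16")
  if (!is_count(n_vessels) || n_vessels < 0)
    stopf("n_vessels must be a nonnegative integer")
  nz <- grid_shape[1]; nx <- grid_shape[2]
  v_bound <- aliasing_velocity_bound(acq)
  if (max(abs(velocity_range)) * (1 + 3 * velocity_jitter) >= v_bound)
    stopf(
      "vessel velocity up to %.4g m/s would alias: slow-time Nyquist bound is %.4g m/s",
      max(abs(velocity_range)), v_bound)

  with_seed(seed, {
    # smooth positive tissue field in [0.7, 1.3] x amplitude
    u <- matrix(stats::rnorm(nz * nx), nz, nx)
    kz <- stats::dnorm(seq(-12, 12), sd = 4); kz <- kz / sum(kz)
    cm_z <- conv_matrix_reflect(nz, kz)
    cm_x <- conv_matrix_reflect(nx, kz)
    u <- cm_z %*% u %*% t(cm_x)
    u <- (u - min(u)) / max(max(u) - min(u), 1e-12)
    tissue <- tissue_amplitude * (0.7 + 0.6 * u)

    segments <- list()
    occupied <- matrix(FALSE, nz, nx)
    half <- vessel_width_px / 2
    for (v in seq_len(n_vessels)) {
      horizontal <- (v %% 2L) == 1L
      n_along <- if (horizontal) nx else nz
      n_across <- if (horizontal) nz else nx
      c0 <- stats::runif(1, 0.2, 0.8) * n_across
      amp <- stats::runif(1, 0, 0.08) * n_across
      ph <- stats::runif(1, 0, 2 * pi)
      cyc <- stats::runif(1, 0.5, 1.5)
      center <- c0 + amp * sin(2 * pi * cyc * seq_len(n_along) / n_along + ph)
      across <- matrix(seq_len(n_across), n_across, n_along)
      dist <- abs(across - matrix(center, n_across, n_along, byrow = TRUE))
      mask_ao <- dist <= half
      # alternate flow direction between vessels (artery/vein pairing);
      # keeps their Doppler bands on opposite sides of the spectrum
      v_peak <- stats::runif(1, velocity_range[1], velocity_range[2]) *
        if (v %% 2L == 1L) 1 else -1
      prof <- if (flow_profile == "parabolic") {
        pmax(1 - (dist / (half + 0.3))^2, 0.05)
      } else {
        matrix(1, n_across, n_along)
      }
      vmap_ao <- v_peak * prof *
        (1 + velocity_jitter * matrix(stats::rnorm(n_across * n_along),
                                      n_across, n_along))
      vmap_ao[!mask_ao] <- 0
      if (horizontal) { mask <- mask_ao; vmap <- vmap_ao }
      else { mask <- t(mask_ao); vmap <- t(vmap_ao) }
      mask <- mask & !occupied  # first vessel wins at crossings
      vmap[!mask] <- 0
      occupied <- occupied | mask
      segments[[v]] <- list(mask = mask, axial_velocity = v_peak,
                            blood_amplitude = blood_amplitude,
                            velocity_map = vmap, speckle = speckle)
    }
    tissue[occupied] <- 0  # vessel lumen carries blood, not tissue
    activation <- matrix(FALSE, nz, nx)
    if (effect_size > 0 && n_vessels >= 1L)
      activation <- segments[[1L]]$mask
    phantom_scene(grid_shape, tissue, segments, activation,
                  effect_size, noise_sigma)
  })
}

# Stimulus-locked fractional CBV time course at an arbitrary clock:
# effect_size x (stimulus boxcar convolved with the gamma HRF,
# peak-normalized). Zero when there are no stimuli or effect_size == 0.
cbv_timecourse <- function(times, protocol, hrf, effect_size) {
  if (effect_size == 0 || length(protocol$onsets) == 0L)
    return(numeric(length(times)))
  dt <- if (length(times) > 1L) times[2] - times[1] else 1
  box <- rep(0, length(times))
  for (i in seq_along(protocol$onsets)) {
    on <- protocol$onsets[i]
    box[times >= on & times < on + protocol$durations[i]] <- 1
  }
  kern <- gamma_hrf(hrf, dt = dt, duration = 15)
  y <- stats::convolve(box, rev(kern), type = "open")[seq_along(times)]
  m <- max(y)
  if (m <= 0) return(numeric(length(times)))
  effect_size * y / m
}

# Shared signal synthesis at the compounded clock. Returns the complex
# (n_frames x n_pixels) signal matrix (column-major pixel order, z fastest),
# before additive receiver noise. Motion (when present) displaces the
# tissue/clutter field only: flowing-blood speckle regenerates on a
# millisecond timescale, so sub-pixel lumen displacement has no effect on
# it, whereas envelope-domain resampling of the blood process would
# introduce a nonphysical power attenuation; receiver noise enters after
# any tissue displacement.
simulate_signal_matrix <- function(scene, protocol, acq, hrf, motion) {
  nz <- scene$grid_shape[1]; nx <- scene$grid_shape[2]
  rate <- acq$compound_frame_rate
  ntc <- floor(protocol$total_duration * rate)
  block_dur <- acq$frames_per_block / rate
  if (protocol$total_duration < block_dur)
    stopf("protocol (%.3g s) is shorter than one Doppler block (%.3g s)",
          protocol$total_duration, block_dur)
  tt <- (seq_len(ntc) - 1) / rate

  # tissue: amplitude map x static speckle phase (spatially smooth at the
  # ~1.5 px speckle-cell scale) x rank-<=3 temporal modulation (constant +
  # two smooth seeded basis functions)
  mod <- 1 + 0.02 * smooth_noise(ntc, 1 / rate, 2) +
    0.02 * smooth_noise(ntc, 1 / rate, 0.7)
  ph <- matrix(stats::rnorm(nz * nx), nz, nx)
  kp <- stats::dnorm(seq(-6, 6), sd = 1.5); kp <- kp / sum(kp)
  ph <- conv_matrix_reflect(nz, kp) %*% ph %*% t(conv_matrix_reflect(nx, kp))
  phase <- 3 * ph / stats::sd(ph)
  tis <- as.vector(scene$tissue_amplitude * exp(1i * phase))
  sig <- rep(tis, each = ntc)  # outer(mod, tis) built without a copy
  dim(sig) <- c(ntc, length(tis))
  step <- max(1L, ceiling(ncol(sig) / 16))
  for (j0 in seq(1L, ncol(sig), by = step)) {  # in-place, chunked
    jj <- j0:min(j0 + step - 1L, ncol(sig))
    sig[, jj] <- sig[, jj] * mod
  }

  mp <- make_motion_path(motion, nz, nx, ntc, rate)
  sig <- apply_motion(sig, mp, nz, nx)

  # blood: per-pixel Doppler rotation f_d = 2 v f_c / c on the compounded
  # slow-time clock; activated pixels scale as sqrt(1 + dCBV(t)) so power
  # Doppler scales as 1 + dCBV(t)
  cbv <- cbv_timecourse(tt, protocol, hrf, scene$effect_size)
  amp_active <- sqrt(1 + cbv)
  v_bound <- aliasing_velocity_bound(acq)
  for (v in scene$vessel_segments) {
    vmap <- v$velocity_map
    if (is.null(vmap)) {
      vmap <- matrix(0, nz, nx); vmap[v$mask] <- v$axial_velocity
    }
    if (max(abs(vmap)) >= v_bound)
      stopf("vessel velocity %.4g m/s aliases on the %g Hz slow-time clock (bound %.4g m/s)",
            max(abs(vmap)), rate, v_bound)
    idx <- which(v$mask)
    if (!length(idx)) next
    fd <- 2 * vmap[idx] * acq$center_frequency / acq$speed_of_sound
    th0 <- stats::runif(length(idx), 0, 2 * pi)
    act <- scene$activation_mask[idx]
    use_speckle <- isTRUE(v$speckle)
    # speckle correlation time ~ blood transit through the half-pixel
    # speckle cell (in-plane plus elevational components)
    spacing <- min(acq$pixel_spacing_z, acq$pixel_spacing_x)
    tau_c <- pmin(pmax(spacing / (3 * pmax(abs(vmap[idx]), 1e-4)), 0.003), 0.008)
    for (j in seq_along(idx)) {
      carrier <- exp(1i * (2 * pi * fd[j] * tt + th0[j]))
      if (use_speckle) {
        carrier <- carrier * ar1_speckle(length(tt), 1 / rate, tau_c[j])
      }
      a <- if (act[j]) v$blood_amplitude * amp_active else v$blood_amplitude
      sig[, idx[j]] <- sig[, idx[j]] + a * carrier
    }
  }
  list(sig = sig, ntc = ntc, times = tt, cbv = cbv, motion_path = mp)
}

# Seeded motion fields and temporal path; displacement of frame 1 is zero
# and |displacement| <= max_displacement_px everywhere.
make_motion_path <- function(motion, nz, nx, ntc, rate) {
  if (motion$kind == "none" || motion$max_displacement_px == 0)
    return(NULL)
  gz <- smooth_noise(ntc, 1 / rate, motion$temporal_scale_s)
  gx <- smooth_noise(ntc, 1 / rate, motion$temporal_scale_s)
  gz <- gz - gz[1]; gx <- gx - gx[1]
  gmax <- max(abs(c(gz, gx)), 1e-12)
  gz <- gz / gmax; gx <- gx / gmax
  if (motion$kind == "rigid") {
    fz <- matrix(1, nz, nx); fx <- matrix(1, nz, nx)
  } else {
    blur_field <- function() {
      f <- matrix(stats::rnorm(nz * nx), nz, nx)
      k <- stats::dnorm(seq(-3, 3) * motion$spatial_scale_px / 2,
                        sd = motion$spatial_scale_px)
      k <- k / sum(k)
      f <- conv_matrix_reflect(nz, k) %*% f %*% t(conv_matrix_reflect(nx, k))
      f / max(abs(f), 1e-12)
    }
    fz <- blur_field(); fx <- blur_field()
  }
  list(fz = fz * motion$max_displacement_px,
       fx = fx * motion$max_displacement_px, gz = gz, gx = gx)
}

# Warp every frame by its displacement field. The temporal path is smooth,
# so it is quantized (default quantum 1% of the path range, i.e. <= 0.01 x
# max_displacement pixels of positional error) and frames sharing a
# quantized displacement are warped together with vectorized gathers.
apply_motion <- function(sig, mp, nz, nx, quantum = 0.01) {
  if (is.null(mp)) return(sig)
  gz_q <- round(mp$gz / quantum) * quantum
  gx_q <- round(mp$gx / quantum) * quantum
  key <- paste(gz_q, gx_q)
  grid_z <- as.vector(matrix(seq_len(nz), nz, nx))
  grid_x <- as.vector(matrix(seq_len(nx), nz, nx, byrow = TRUE))
  fzv <- as.vector(mp$fz); fxv <- as.vector(mp$fx)
  for (k in unique(key)) {
    rows <- which(key == k)
    gz <- gz_q[rows[1]]; gx <- gx_q[rows[1]]
    if (gz == 0 && gx == 0) next
    zi <- pmin(pmax(grid_z - fzv * gz, 1), nz)
    xi <- pmin(pmax(grid_x - fxv * gx, 1), nx)
    z0 <- pmin(floor(zi), nz - 1L); x0 <- pmin(floor(xi), nx - 1L)
    fz <- zi - z0; fx <- xi - x0
    i00 <- z0 + (x0 - 1) * nz
    w00 <- (1 - fz) * (1 - fx); w10 <- fz * (1 - fx)
    w01 <- (1 - fz) * fx;       w11 <- fz * fx
    sub <- sig[rows, , drop = FALSE]
    sig[rows, ] <-
      sub[, i00, drop = FALSE] * rep(w00, each = length(rows)) +
      sub[, i00 + 1, drop = FALSE] * rep(w10, each = length(rows)) +
      sub[, i00 + nz, drop = FALSE] * rep(w01, each = length(rows)) +
      sub[, i00 + nz + 1, drop = FALSE] * rep(w11, each = length(rows))
  }
  sig
}

#' Simulate a compounded complex frame sequence from a phantom scene
#'
#' Generates the slow-time complex frame stack at the compounded frame rate
#' (post compounding and temporal averaging): tissue clutter with a
#' rank-<=3 temporal modulation, per-vessel-pixel Doppler phase rotation at
#' `f_d = 2 v f_c / c`, a stimulus-locked CBV amplitude modulation on
#' activated pixels, additive complex white noise, and optional nonrigid or
#' rigid motion. Fully reproducible given the seed.
#'
#' @param scene A [phantom_scene()] / [make_phantom()] scene.
#' @param protocol A [stimulus_protocol()]; must cover at least one Doppler
#'   block.
#' @param acq [acq_params()].
#' @param hrf [hrf_params()] shaping the CBV response.
#' @param motion [motion_model()].
#' @param seed Integer seed.
#' @return Object of class `fus_compound_seq`: `$frames` is a complex array
#'   `(time, z, x)` at `acq$compound_frame_rate`, `$acq` the acquisition
#'   metadata. The attribute `"truth"` carries the ground-truth fractional
#'   CBV time course and the motion path.
#' @export
simulate_compound_frames <- function(scene, protocol, acq = acq_params(),
                                     hrf = hrf_params(),
                                     motion = motion_model(), seed = 1L) {
  nz <- scene$grid_shape[1]; nx <- scene$grid_shape[2]
  with_seed(seed, {
    core <- simulate_signal_matrix(scene, protocol, acq, hrf, motion)
    sig <- core$sig
    core$sig <- NULL  # single reference: noise add and reshape stay in place
    if (scene$noise_sigma > 0) {
      sd2 <- scene$noise_sigma / sqrt(2)
      npx <- ncol(sig)
      step <- max(1L, ceiling(npx / 16))
      for (j0 in seq(1L, npx, by = step)) {
        jj <- j0:min(j0 + step - 1L, npx)
        nlen <- length(jj) * nrow(sig)
        sig[, jj] <- sig[, jj] +
          complex(real = stats::rnorm(nlen, sd = sd2),
                  imaginary = stats::rnorm(nlen, sd = sd2))
      }
    }
    dim(sig) <- c(core$ntc, nz, nx)
    structure(
      list(frames = sig, acq = acq),
      class = "fus_compound_seq",
      truth = list(cbv = core$cbv, times = core$times,
                   motion = core$motion_path, seed = seed)
    )
  })
}

#' Simulate a per-angle complex frame sequence
#'
#' Expands the compounded-clock signal of [simulate_compound_frames()] to
#' the pre-averaging acquisition stream: every compounded frame is
#' represented by `temporal_averaging_factor` consecutive frames for each
#' transmit angle, carrying the same slow-time signal value (the Doppler
#' phase clock is the compounded frame clock) plus independent complex
#' noise at `noise_sigma * sqrt(n_angles * factor)` per raw frame, so that
#' compounding + temporal averaging recovers the compounded statistics.
#'
#' Intended for exercising [compound_angles()] and [temporal_average()];
#' memory grows with `n_angles * factor`, so use small grids/durations.
#'
#' @inheritParams simulate_compound_frames
#' @return Object of class `fus_angle_seq`: `$frames` is a complex array
#'   `(time, angle, z, x)` at `compound_frame_rate * factor` per angle.
#' @export
simulate_angle_frames <- function(scene, protocol, acq = acq_params(),
                                  hrf = hrf_params(),
                                  motion = motion_model(), seed = 1L) {
  nz <- scene$grid_shape[1]; nx <- scene$grid_shape[2]
  na <- length(acq$angles_deg)
  fac <- acq$temporal_averaging_factor
  with_seed(seed, {
    core <- simulate_signal_matrix(scene, protocol, acq, hrf, motion)
    sig <- core$sig
    ntr <- core$ntc * fac
    raw <- sig[rep(seq_len(core$ntc), each = fac), , drop = FALSE]
    frames <- array(0i, dim = c(ntr, na, nz, nx))
    sd_raw <- scene$noise_sigma * sqrt(na * fac) / sqrt(2)
    for (a in seq_len(na)) {
      pa <- raw
      if (scene$noise_sigma > 0) {
        n <- length(pa)
        pa <- pa + complex(real = stats::rnorm(n, sd = sd_raw),
                           imaginary = stats::rnorm(n, sd = sd_raw))
      }
      frames[, a, , ] <- array(pa, dim = c(ntr, nz, nx))
    }
    structure(
      list(frames = frames, acq = acq),
      class = "fus_angle_seq",
      truth = list(cbv = core$cbv, times = core$times,
                   motion = core$motion_path, seed = seed)
    )
  })
}

#' @export
print.fus_compound_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Compounded complex sequence: %d frames of %d x %d at %g Hz\n",
              d[1], d[2], d[3], x$acq$compound_frame_rate))
  invisible(x)
}

#' @export
print.fus_angle_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Per-angle complex sequence: %d frames x %d angles of %d x %d at %g Hz per angle\n",
    d[1], d[2], d[3], d[4],
    x$acq$compound_frame_rate * x$acq$temporal_averaging_factor))
  invisible(x)
}
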