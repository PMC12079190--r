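# Shared fixtures and independent oracles. Everything is generated in code;
# the expensive end-to-end run is computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Wrap a plain (time, z, x) array as a power Doppler series object.
as_pd_series <- function(images, block_rate = 2,
                         spacing = 2e-4) {
  structure(list(
    images = images,
    block_rate = block_rate,
    block_timestamps = (seq_len(dim(images)[1]) - 0.5) / block_rate,
    pixel_spacing_z = spacing, pixel_spacing_x = spacing,
    singular_values = NULL,
    provenance = list(svd_fraction = NA, frames_per_block = NA)
  ), class = "fus_pd_series")
}

# Single-vessel scene with uniform (plug) velocity and optional speckle,
# for analytic Doppler checks.
plug_scene <- function(grid = c(16L, 16L), velocity = 0.012,
                       tissue_amplitude = 0, noise_sigma = 0,
                       blood_amplitude = 1, speckle = FALSE,
                       effect_size = 0) {
  mask <- matrix(FALSE, grid[1], grid[2])
  mask[8:10, ] <- TRUE
  vmap <- matrix(0, grid[1], grid[2])
  vmap[mask] <- velocity
  act <- matrix(FALSE, grid[1], grid[2])
  if (effect_size > 0) act <- mask
  phantom_scene(
    grid_shape = grid,
    tissue_amplitude = matrix(tissue_amplitude, grid[1], grid[2]),
    vessel_segments = list(list(mask = mask, axial_velocity = velocity,
                                blood_amplitude = blood_amplitude,
                                velocity_map = vmap, speckle = speckle)),
    activation_mask = act,
    effect_size = effect_size,
    noise_sigma = noise_sigma
  )
}

# One-block protocol with no stimuli (for resting Doppler runs).
rest_protocol <- function(duration = 1) {
  stimulus_protocol(duration, numeric(0), numeric(0), duration)
}

# Full default-conditions run (auditory protocol, 10% effect, default
# motion/noise) on a 32 x 32 grid; cached across test files.
full_run <- function() {
  if (!is.null(.fixture_cache$full)) return(.fixture_cache$full)
  acq <- acq_params()
  scene <- make_phantom(c(32L, 32L), n_vessels = 2L, effect_size = 0.10,
                        seed = 1L, acq = acq)
  protocol <- default_protocol()
  seq <- simulate_compound_frames(scene, protocol, acq, seed = 2L)
  pd <- doppler_movie(seq)
  act <- activation_pipeline(pd, protocol)
  .fixture_cache$full <- list(acq = acq, scene = scene, protocol = protocol,
                              pd = pd, act = act,
                              series = attr(act, "series"))
  .fixture_cache$full
}

# Frobenius norm that is correct for complex matrices.
fnorm <- function(m) sqrt(sum(Mod(m)^2))

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg by exhaustive step-up search: the largest k with
# p_(k) <= q k / m determines the rejection set; adjusted values by the
# defining minimum.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[ord][i:m] * m / (i:m)
    adj[ord[i]] <- min(cand, 1)
  }
  adj
}

# Clutter filter by explicit outer-product subtraction of the top-k
# components.
svd_filter_oracle <- function(m, k) {
  sv <- svd(m)
  out <- m
  for (i in seq_len(k)) {
    out <- out - sv$d[i] * sv$u[, i] %*% Conj(t(sv$v[, i, drop = FALSE]))
  }
  out
}

# GLM slope/t/p by explicit normal equations, one voxel at a time.
glm_oracle <- function(y, x) {
  xtx <- t(x) %*% x
  b <- solve(xtx, t(x) %*% y)
  res <- y - x %*% b
  dof <- nrow(x) - ncol(x)
  s2 <- sum(res^2) / dof
  se <- sqrt(s2 * solve(xtx)[1, 1])
  tt <- b[1] / se
  list(beta = b[1], t = tt, p = 2 * stats::pt(-abs(tt), dof))
}

# ROI selection by brute-force scan over all candidate windows.
select_rois_oracle <- function(tmap, pd_mean, nr, nc, vq = 0.7) {
  wm <- matrix(NA_real_, nrow(tmap) - nr + 1L, ncol(tmap) - nc + 1L)
  for (r0 in seq_len(nrow(wm))) for (c0 in seq_len(ncol(wm)))
    wm[r0, c0] <- mean(pd_mean[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)])
  thr <- stats::quantile(wm, vq, names = FALSE)
  best_r <- NULL; best_n <- NULL
  best_r_key <- -Inf; best_n_key <- Inf
  for (r0 in seq_len(nrow(tmap) - nr + 1L)) {
    for (c0 in seq_len(ncol(tmap) - nc + 1L)) {
      w <- tmap[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)]
      v <- mean(pd_mean[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)])
      if (v < thr) next
      if (mean(w) > best_r_key) { best_r_key <- mean(w); best_r <- c(r0, c0) }
      if (mean(abs(w)) < best_n_key) { best_n_key <- mean(abs(w)); best_n <- c(r0, c0) }
    }
  }
  list(reactive = best_r, nonreactive = best_n)
}
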