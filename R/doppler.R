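# Doppler core: coherent compounding, temporal averaging, Casorati/SVD
# clutter filtering, power Doppler block series, plane stacking.

#' Coherently compound per-angle frames
#'
#' Coherent (complex) mean across the transmit-angle axis.
#'
#' @param seq A `fus_angle_seq` (see [simulate_angle_frames()] or
#'   [read_frames()]).
#' @return Complex array `(time, z, x)` at the per-angle frame rate.
#' @export
compound_angles <- function(seq) {
  stopifnot(inherits(seq, "fus_angle_seq"))
  d <- dim(seq$frames)
  na <- d[2]
  if (na != length(seq$acq$angles_deg))
    stopf("angle axis (%d) does not match acq$angles_deg (%d)",
          na, length(seq$acq$angles_deg))
  out <- seq$frames[, 1, , ]
  if (na > 1) {
    for (a in 2:na) out <- out + seq$frames[, a, , ]
  }
  dim(out) <- d[c(1, 3, 4)]
  out / na
}

#' Non-overlapping temporal averaging
#'
#' Averages every `factor` consecutive frames, reducing the frame rate by
#' `factor` ("triple temporal averaging" at the default acquisition). A
#' trailing remainder shorter than `factor` is truncated.
#'
#' @param frames Complex array `(time, z, x)`.
#' @param factor Positive integer averaging factor; 1 is the identity.
#' @param acq Optional [acq_params()] carried through to the result.
#' @return Object of class `fus_compound_seq` with `$frames` at the reduced
#'   rate (interpreted as `acq$compound_frame_rate` when `acq` is given).
#' @export
temporal_average <- function(frames, factor, acq = NULL) {
  if (!is_count(factor) || factor < 1) stopf("factor must be a positive integer")
  d <- dim(frames)
  stopifnot(length(d) == 3L)
  factor <- as.integer(factor)
  ntc <- d[1] %/% factor
  if (ntc < 1L) stopf("fewer frames (%d) than the averaging factor", d[1])
  if (d[1] %% factor != 0L)
    message(sprintf("temporal_average: truncating %d trailing frame(s)",
                    d[1] %% factor))
  x <- frames[seq_len(ntc * factor), , , drop = FALSE]
  dim(x) <- c(factor, ntc, d[2] * d[3])
  out <- colMeans(x)
  dim(out) <- c(ntc, d[2], d[3])
  structure(list(frames = out, acq = acq), class = "fus_compound_seq")
}

#' Casorati matrix of a frame block
#'
#' Rearranges a complex block `(time, z, x)` into the space x slow-time
#' Casorati matrix used for SVD clutter filtering. Column `k` is frame `k`
#' flattened in row-major order over `(z, x)`: pixel index
#' `p = (z - 1) * nx + x` (x varies fastest). [casorati_to_stack()] inverts
#' the rearrangement exactly.
#'
#' @param block Complex array `(nt, nz, nx)` with `nt >= 2`.
#' @return Complex matrix `(nz * nx) x nt`.
#' @export
build_casorati <- function(block) {
  d <- dim(block)
  stopifnot(length(d) == 3L)
  if (d[1] < 2L) stopf("a Casorati block needs at least 2 frames")
  m <- aperm(block, c(3, 2, 1))  # (x, z, t): x fastest within a column
  dim(m) <- c(d[2] * d[3], d[1])
  m
}

#' @rdname build_casorati
#' @param casorati Matrix produced by `build_casorati()`.
#' @param nz,nx Grid shape to restore.
#' @export
casorati_to_stack <- function(casorati, nz, nx) {
  nt <- ncol(casorati)
  stopifnot(nrow(casorati) == nz * nx)
  a <- casorati
  dim(a) <- c(nx, nz, nt)
  aperm(a, c(3, 2, 1))
}

#' SVD clutter filter
#'
#' Removes the tissue (clutter) subspace from a Casorati matrix: the full
#' singular value decomposition is computed and the `k = floor(svd_fraction
#' * nt)` lowest-order components (largest singular values, where the
#' high-amplitude, temporally coherent tissue signal concentrates) are
#' zeroed before reconstruction. The default fraction 0.13 removes 32 of
#' 250 components per block.
#'
#' @param casorati Complex (or numeric) matrix, pixels x slow-time.
#' @param svd_fraction Fraction in `[0, 1)` of slow-time components to
#'   remove (default 0.13); 0 returns the input unchanged.
#' @return List with `filtered` (same shape as input), `singular_values`
#'   (all singular values, decreasing), `k` (number of components removed)
#'   and `svd_fraction`.
#' @export
svd_clutter_filter <- function(casorati, svd_fraction = 0.13) {
  if (svd_fraction < 0 || svd_fraction >= 1)
    stopf("svd_fraction must be in [0, 1)")
  if (any(!is.finite(Re(casorati))) || any(!is.finite(Im(casorati))))
    stopf("casorati matrix contains non-finite entries")
  nt <- ncol(casorati)
  k <- floor(svd_fraction * nt)
  sv <- svd(casorati, nu = 0)
  if (k == 0) {
    return(list(filtered = casorati, singular_values = sv$d, k = 0L,
                svd_fraction = svd_fraction))
  }
  kk <- min(k, ncol(sv$v))
  vk <- sv$v[, seq_len(kk), drop = FALSE]
  # X = U D V^H, so removing the top-k components is the right-projection
  # X (I - V_k V_k^H)
  filtered <- casorati - (casorati %*% vk) %*% Conj(t(vk))
  list(filtered = filtered, singular_values = sv$d, k = as.integer(k),
       svd_fraction = svd_fraction)
}

#' Power Doppler image of a frame block
#'
#' Per-pixel temporal mean of the squared signal magnitude; proportional to
#' the moving-blood volume in the pixel once clutter has been removed.
#'
#' @param x Complex array `(nt, nz, nx)` or a Casorati matrix (pixels x nt,
#'   with `nz`, `nx` supplied to reshape the result).
#' @param nz,nx Grid shape when `x` is a Casorati matrix.
#' @return Nonnegative numeric matrix `(nz, nx)`.
#' @export
power_doppler <- function(x, nz = NULL, nx = NULL) {
  if (is.matrix(x)) {
    stopifnot(!is.null(nz), !is.null(nx), nrow(x) == nz * nx)
    pd <- rowMeans(Re(x)^2 + Im(x)^2)
    dim(pd) <- c(nx, nz)
    return(t(pd))
  }
  d <- dim(x)
  stopifnot(length(d) == 3L)
  m <- Re(x)^2 + Im(x)^2
  dim(m) <- c(d[1], d[2] * d[3])
  pd <- colMeans(m)
  dim(pd) <- c(d[2], d[3])
  pd
}

#' Decibel view of a power Doppler image
#'
#' `10 * log10(pd / max(pd))`, the conventional display scaling.
#'
#' @param pd Nonnegative power Doppler image.
#' @return Matrix of dB values (<= 0).
#' @export
power_doppler_db <- function(pd) {
  m <- max(pd)
  if (m <= 0) stopf("power Doppler image has no positive values")
  10 * log10(pmax(pd, .Machine$double.xmin) / m)
}

#' Power Doppler block series
#'
#' Full Doppler core: (optionally) compound per-angle frames and apply
#' temporal averaging, then cut the compounded stream into non-overlapping
#' blocks of `frames_per_block` frames aligned to the acquisition start and
#' SVD-filter each block's Casorati matrix before computing its power
#' Doppler image. 250-frame blocks at 500 Hz give the standard 2 Hz series.
#'
#' @param seq A `fus_angle_seq` or `fus_compound_seq`.
#' @param svd_fraction Clutter-filter fraction (default 0.13), applied per
#'   block.
#' @param frames_per_block Compounded frames per block (default from
#'   `seq$acq`).
#' @return Object of class `fus_pd_series`: `$images` is a nonnegative
#'   array `(block_time, z, x)`, `$block_rate` in Hz, `$block_timestamps`
#'   the block-center times in seconds, `$singular_values` a matrix (one
#'   column per block) and `$provenance` the filter settings.
#' @export
doppler_movie <- function(seq, svd_fraction = 0.13, frames_per_block = NULL) {
  if (inherits(seq, "fus_angle_seq")) {
    comp <- compound_angles(seq)
    seq <- temporal_average(comp, seq$acq$temporal_averaging_factor,
                            acq = seq$acq)
  }
  stopifnot(inherits(seq, "fus_compound_seq"))
  acq <- seq$acq
  if (is.null(acq)) stopf("sequence carries no acquisition metadata")
  fpb <- as.integer(frames_per_block %||% acq$frames_per_block)
  d <- dim(seq$frames)
  nb <- d[1] %/% fpb
  if (nb < 1L)
    stopf("need at least %d compounded frames for one block, got %d",
          fpb, d[1])
  rate <- acq$compound_frame_rate
  nz <- d[2]; nx <- d[3]
  images <- array(0, dim = c(nb, nz, nx))
  svals <- NULL
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * fpb + 1L):(b * fpb)
    cas <- build_casorati(seq$frames[idx, , , drop = FALSE])
    f <- svd_clutter_filter(cas, svd_fraction)
    images[b, , ] <- power_doppler(f$filtered, nz = nz, nx = nx)
    if (is.null(svals))
      svals <- matrix(0, length(f$singular_values), nb)
    svals[, b] <- f$singular_values
  }
  structure(list(
    images = images,
    block_rate = rate / fpb,
    block_timestamps = (seq_len(nb) - 0.5) * fpb / rate,
    pixel_spacing_z = acq$pixel_spacing_z,
    pixel_spacing_x = acq$pixel_spacing_x,
    singular_values = svals,
    provenance = list(svd_fraction = svd_fraction, frames_per_block = fpb,
                      components_removed = floor(svd_fraction * fpb),
                      angles_deg = acq$angles_deg,
                      compound_frame_rate = rate)
  ), class = "fus_pd_series")
}

#' @export
print.fus_pd_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "Power Doppler series: %d frames of %d x %d at %g Hz (SVD fraction %.3g, %d frames/block)\n",
    d[1], d[2], d[3], x$block_rate, x$provenance$svd_fraction,
    x$provenance$frames_per_block))
  invisible(x)
}

#' Stack scanned planes into a volume series
#'
#' Assembles power Doppler series acquired at successive probe positions
#' (sequential plane scanning) into a 4-D container ordered by position.
#' Unsorted inputs are stored sorted; `$order` maps stored planes back to
#' the input indices.
#'
#' @param series_list List of `fus_pd_series` with identical grid shapes
#'   and block counts.
#' @param positions Numeric plane positions along the scan axis in meters
#'   (strictly monotone after sorting, i.e. no duplicates).
#' @return Object of class `fus_volume_series` with `$volumes` array
#'   `(plane, block_time, z, x)`, `$positions` (sorted), `$order`.
#' @export
stack_planes <- function(series_list, positions) {
  if (length(series_list) != length(positions))
    stopf("need one position per plane")
  if (anyDuplicated(positions)) stopf("plane positions must be distinct")
  dims <- lapply(series_list, function(s) dim(s$images))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("all planes must share grid shape and block count")
  ord <- order(positions)
  d <- dims[[1]]
  vol <- array(0, dim = c(length(ord), d))
  for (i in seq_along(ord)) vol[i, , , ] <- series_list[[ord[i]]]$images
  structure(list(
    volumes = vol,
    positions = positions[ord],
    order = ord,
    block_rate = series_list[[1]]$block_rate,
    block_timestamps = series_list[[1]]$block_timestamps
  ), class = "fus_volume_series")
}
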