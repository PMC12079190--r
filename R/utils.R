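# Internal helpers shared across the pipeline. None exported.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Unit-variance, zero-mean smooth random series: white Gaussian noise
# convolved with a Gaussian kernel of standard deviation tau seconds.
# Correlation time ~ tau; used for tissue modulation and motion paths.
smooth_noise <- function(n, dt, tau) {
  sd_samp <- max(tau / dt, 1e-6)
  r <- ceiling(4 * sd_samp)
  x <- stats::rnorm(n + 2L * r)
  k <- stats::dnorm(seq(-r, r), sd = sd_samp)
  k <- k / sum(k)
  y <- stats::convolve(x, rev(k), type = "open")
  y <- y[(2L * r + 1L):(2L * r + n)]
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# 1-D convolution matrix with symmetric (reflective) boundary handling:
# out-of-range index j maps to 1 - j (left) or 2n + 1 - j (right).
conv_matrix_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  reflect <- function(j) {
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 2L - j, j)
      j <- ifelse(j > n, 2L * n - j, j)
    }
    j
  }
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- reflect(i + seq(-r, r))
    for (u in seq_along(idx)) cm[i, idx[u]] <- cm[i, idx[u]] + kernel[u]
  }
  cm
}

# Bilinear sampling of a (possibly complex) image at fractional positions,
# clamped to the image border (edge replication).
bilinear_sample <- function(img, zi, xi) {
  nz <- nrow(img)
  nx <- ncol(img)
  zi <- pmin(pmax(zi, 1), nz)
  xi <- pmin(pmax(xi, 1), nx)
  z0 <- pmin(floor(zi), nz - 1L)
  x0 <- pmin(floor(xi), nx - 1L)
  fz <- zi - z0
  fx <- xi - x0
  z0 <- as.integer(z0); x0 <- as.integer(x0)
  img[cbind(z0, x0)] * (1 - fz) * (1 - fx) +
    img[cbind(z0 + 1L, x0)] * fz * (1 - fx) +
    img[cbind(z0, x0 + 1L)] * (1 - fz) * fx +
    img[cbind(z0 + 1L, x0 + 1L)] * fz * fx
}

# Translate an image by (dz, dx) pixels (content moves by +dz down, +dx
# right), bilinear interpolation with edge replication.
shift_image <- function(img, dz, dx) {
  nz <- nrow(img)
  nx <- ncol(img)
  grid_z <- matrix(seq_len(nz), nz, nx)
  grid_x <- matrix(seq_len(nx), nz, nx, byrow = TRUE)
  out <- bilinear_sample(img, grid_z - dz, grid_x - dx)
  dim(out) <- c(nz, nx)
  out
}

# Centered moving average along the first dimension of a (time x voxel)
# matrix; edges use shrinking (truncated) windows. window must be odd.
moving_average_cols <- function(m, window) {
  if (window == 1L) return(m)
  n <- nrow(m)
  h <- (window - 1L) %/% 2L
  cs <- apply(m, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(m))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  (upper - lower) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stationary complex AR(1) (Ornstein-Uhlenbeck) speckle process with
# autocorrelation exp(-|dt|/tau) and E|g|^2 = 1.
ar1_speckle <- function(n, dt, tau) {
  rho <- exp(-dt / tau)
  s <- sqrt(1 - rho^2)
  re <- stats::rnorm(n) / sqrt(2)
  im <- stats::rnorm(n) / sqrt(2)
  re[-1] <- re[-1] * s
  im[-1] <- im[-1] * s
  complex(real = stats::filter(re, rho, method = "recursive"),
          imaginary = stats::filter(im, rho, method = "recursive"))
}

# Row-stochastic matrix equivalent to the centered shrinking-window moving
# average applied by temporal smoothing.
smoothing_matrix <- function(n, window) {
  h <- (window - 1L) %/% 2L
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    s[i, lo:hi] <- 1 / (hi - lo + 1L)
  }
  s
}
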