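# Doppler core: compounding, averaging, Casorati/SVD filtering, power
# Doppler, plane stacking.

make_angle_seq <- function(frames, acq) {
  structure(list(frames = frames, acq = acq), class = "fus_angle_seq")
}

test_that("coherent compounding averages the angle axis", {
  acq <- acq_params(angles_deg = c(-6, -4, -2, 0, 2, 4, 6))
  f <- array(0i, dim = c(2, 7, 4, 4))
  base <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  for (a in 1:7) for (t in 1:2) f[t, a, , ] <- base
  out <- compound_angles(make_angle_seq(f, acq))
  expect_equal(out[1, , ], base)

  acq2 <- acq_params(angles_deg = c(-1, 1))
  f2 <- array(0i, dim = c(1, 2, 4, 4))
  f2[1, 1, , ] <- 1 + 0i
  f2[1, 2, , ] <- -1 + 0i
  expect_equal(max(abs(compound_angles(make_angle_seq(f2, acq2)))), 0)

  expect_error(compound_angles(make_angle_seq(f2, acq)), "does not match")
})

test_that("compounding i.i.d. noise across 7 angles reduces variance to 1/7", {
  set.seed(11)
  acq <- acq_params()
  n <- 60 * 7 * 40 * 40
  f <- array(complex(real = rnorm(n, sd = sqrt(0.5)),
                     imaginary = rnorm(n, sd = sqrt(0.5))),
             dim = c(60, 7, 40, 40))
  out <- compound_angles(make_angle_seq(f, acq))
  v <- mean(Mod(out)^2)  # > 9e4 samples
  expect_equal(v, 1 / 7, tolerance = 0.05)
})

test_that("temporal averaging reduces the rate and averages frames", {
  x <- array(0i, dim = c(3, 2, 2))
  x[1, , ] <- 1; x[2, , ] <- 2; x[3, , ] <- 3
  out <- temporal_average(x, 3)
  expect_equal(dim(out$frames), c(1L, 2L, 2L))
  expect_equal(Re(out$frames[1, 1, 1]), 2)

  y <- array(complex(real = rnorm(3 * 4 * 1500), imaginary = rnorm(3 * 4 * 1500)),
             dim = c(1500, 3, 4))
  expect_identical(temporal_average(y, 1)$frames, y)
  expect_equal(dim(temporal_average(y, 3)$frames)[1], 500L)
  expect_error(temporal_average(y, 0), "positive integer")
  expect_message(temporal_average(y[1:1499, , , drop = FALSE], 3), "truncating")
})

test_that("Casorati construction is shape-correct and invertible", {
  x <- array(complex(real = rnorm(12), imaginary = rnorm(12)), dim = c(3, 2, 2))
  cas <- build_casorati(x)
  expect_equal(dim(cas), c(4L, 3L))
  expect_identical(casorati_to_stack(cas, 2, 2), x)
  # documented flattening: pixel p = (z-1)*nx + x, x fastest
  expect_equal(cas[2, 1], x[1, 1, 2])
  expect_equal(cas[3, 1], x[1, 2, 1])
  const <- array(1 + 2i, dim = c(5, 3, 3))
  d_const <- svd(build_casorati(const), nu = 0, nv = 0)$d
  expect_equal(sum(d_const > 1e-10 * d_const[1]), 1L)
})

test_that("SVD filter removes floor(fraction x nt) components and reports them", {
  m <- matrix(complex(real = rnorm(40 * 250), imaginary = rnorm(40 * 250)),
              40, 250)
  f <- svd_clutter_filter(m, 0.13)
  expect_identical(f$k, 32L)  # floor(0.13 * 250)
  expect_length(f$singular_values, 40)

  fs <- svd_clutter_filter(matrix(1 + 1i, 30, 10), 0.13)
  expect_lt(fnorm(fs$filtered), 1e-8 * fnorm(matrix(1 + 1i, 30, 10)))

  expect_identical(svd_clutter_filter(m, 0)$filtered, m)
  expect_error(svd_clutter_filter(m, 1), "\\[0, 1\\)")
  m[1, 1] <- NaN
  expect_error(svd_clutter_filter(m, 0.1), "non-finite")
})

test_that("SVD filter matches the outer-product-subtraction oracle", {
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(complex(real = rnorm(50 * 20), imaginary = rnorm(50 * 20)),
                50, 20)
    frac <- sample(c(0.05, 0.13, 0.25, 0.4), 1)
    k <- floor(frac * 20)
    f <- svd_clutter_filter(m, frac)
    o <- svd_filter_oracle(m, k)
    expect_lt(fnorm(f$filtered - o) / fnorm(m), 1e-8)
  }
})

test_that("singular values conserve the block energy", {
  set.seed(22)
  for (i in 1:10) {
    m <- matrix(complex(real = rnorm(200 * 50), imaginary = rnorm(200 * 50)),
                200, 50)
    d <- svd_clutter_filter(m, 0.1)$singular_values
    expect_lt(abs(sum(d^2) - fnorm(m)^2) / fnorm(m)^2, 1e-10)
  }
})

test_that("power Doppler is the temporal mean squared magnitude", {
  z <- array(0i, dim = c(4, 3, 3))
  expect_equal(power_doppler(z), matrix(0, 3, 3))
  u <- array(exp(1i * runif(4 * 3 * 3)), dim = c(4, 3, 3))
  expect_equal(power_doppler(u), matrix(1, 3, 3))
  a <- 2.5
  rot <- array(0i, dim = c(8, 1, 1))
  rot[, 1, 1] <- a * exp(1i * seq(0, 7) * 0.9)
  expect_equal(power_doppler(rot)[1, 1], a^2)
  expect_error(power_doppler_db(matrix(0, 2, 2)), "no positive")
})

test_that("doppler_movie produces the 2 Hz block series", {
  sc <- make_phantom(c(16, 16), 1, 0, seed = 1)
  seq <- simulate_compound_frames(sc, rest_protocol(2), seed = 2)
  pd <- doppler_movie(seq)
  expect_s3_class(pd, "fus_pd_series")
  expect_identical(pd$block_rate, 2)
  expect_equal(dim(pd$images)[1], 4L)  # 2 s x 2 Hz
  expect_true(all(pd$images >= 0))
  expect_true(all(diff(pd$block_timestamps) > 0))
  expect_equal(pd$provenance$components_removed, 32)

  short <- seq
  short$frames <- short$frames[1:100, , , drop = FALSE]
  expect_error(doppler_movie(short), "at least")
})

test_that("vessel power Doppler is linear in blood power", {
  sc1 <- plug_scene(blood_amplitude = 2, speckle = TRUE)
  sc2 <- plug_scene(blood_amplitude = 2 * sqrt(2), speckle = TRUE)
  p <- rest_protocol()
  pd1 <- doppler_movie(simulate_compound_frames(sc1, p, seed = 5,
                                                motion = motion_model("none")))
  pd2 <- doppler_movie(simulate_compound_frames(sc2, p, seed = 5,
                                                motion = motion_model("none")))
  vm <- scene_vessel_mask(sc1)
  r <- mean(apply(pd2$images, c(2, 3), mean)[vm]) /
       mean(apply(pd1$images, c(2, 3), mean)[vm])
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("plane stacking orders planes by position and validates shapes", {
  sc <- make_phantom(c(16, 16), 1, 0, seed = 1)
  seq <- simulate_compound_frames(sc, rest_protocol(), seed = 2)
  pd <- doppler_movie(seq)
  one <- stack_planes(list(pd), 0)
  expect_equal(dim(one$volumes)[1], 1L)

  pds <- list(pd, pd, pd)
  vol <- stack_planes(pds, c(2e-3, 0, 1e-3))
  expect_equal(vol$positions, c(0, 1e-3, 2e-3))
  expect_equal(vol$order, c(2L, 3L, 1L))

  bad <- pd
  bad$images <- bad$images[, 1:8, , drop = FALSE]
  expect_error(stack_planes(list(pd, bad), c(0, 1e-3)), "share")
  expect_error(stack_planes(list(pd, pd), c(0, 0)), "distinct")
})
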