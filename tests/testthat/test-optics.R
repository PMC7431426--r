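test_that("optical_config enforces its invariants", {
  expect_error(optical_config(-0.1, 0.1, 530e-9), "u > 0")
  expect_error(optical_config(0.1, 0.1, 530e-9, sensor_shape = c(8, 64)), ">= 16")
  expect_error(optical_config(0.1, 0.1, 530e-9, grid_oversample = 0), "grid_oversample")
  cfg <- optical_config(0.1, 0.05, 617e-9, c(64, 48), 10e-6, 2L)
  expect_s3_class(cfg, "optical_config")
  expect_identical(cfg$sensor_shape, c(64L, 48L))
})

test_that("transfer-form propagation conserves energy and inverts exactly", {
  f <- gaussian_field()
  g <- fresnel_propagate(f, 0.02)
  expect_lt(abs(field_energy(g) - field_energy(f)) / field_energy(f), 1e-6)
  back <- fresnel_propagate(g, -0.02)
  expect_lt(sqrt(mean(Mod(back$amplitude - f$amplitude)^2)), 1e-9)
  expect_identical(dim(g$amplitude), dim(f$amplitude))
  expect_identical(g$pitch, f$pitch)
})

test_that("a uniform plane wave propagates to a phase-advanced plane wave", {
  n <- 64
  f <- complex_field(matrix(complex(real = 1), n, n), 10e-6, 530e-9)
  g <- fresnel_propagate(f, 0.001, pad_factor = 1)  # periodic boundary: no edges
  expect_equal(Mod(g$amplitude), matrix(1, n, n), tolerance = 1e-9)
  phases <- Arg(g$amplitude)
  expect_lt(diff(range(phases)), 1e-6)  # uniform phase
})

test_that("on-axis intensity behind a circular aperture matches the closed form", {
  # closed-form paraxial result: I(0, z) = 4 sin^2(pi a^2 / (2 lambda z))
  lam <- 530e-9; n <- 256; pitch <- 12e-6
  for (case in list(c(0.06, 3e-4), c(0.1, 3e-4), c(0.1, 4.2e-4))) {
    z <- case[1]; a <- case[2]
    fld <- disc_field(n, pitch, a, lam)
    out <- fresnel_propagate(fld, z, method = "transfer")
    onax <- Mod(out$amplitude[n / 2 + 1, n / 2 + 1])^2
    expected <- 4 * sin(pi * a^2 / (2 * lam * z))^2
    expect_equal(onax, expected, tolerance = 0.05)
  }
})

test_that("the impulse-response form agrees with the closed form at long range", {
  lam <- 530e-9; n <- 256; pitch <- 12e-6; a <- 4.2e-4; z <- 0.25
  fld <- disc_field(n, pitch, a, lam)
  expect_gt(z, max_transfer_distance(fld))   # beyond the transfer-form regime
  out <- fresnel_propagate(fld, z, method = "auto")
  expect_gt(out$pitch, pitch)                # impulse form rescales the grid
  onax <- Mod(out$amplitude[nrow(out$amplitude) / 2 + 1, ncol(out$amplitude) / 2 + 1])^2
  expected <- 4 * sin(pi * a^2 / (2 * lam * z))^2
  expect_equal(onax, expected, tolerance = 0.1)
})

test_that("undersampled transfer-form propagation errors with the valid range", {
  f <- gaussian_field(n = 64, pitch = 5e-6)
  expect_error(fresnel_propagate(f, 1, method = "transfer"),
               "maximum valid distance")
  expect_error(fresnel_propagate(f, 0), "non-zero")
})

test_that("point-source field is a symmetric quadratic-phase wave", {
  cfg <- optical_config(0.1, 0.1, 530e-9, c(64, 64), 10e-6)
  f <- point_source_to_mask(cfg)
  a <- f$amplitude
  # symmetric about the centre index (the even grid drops one border sample)
  sub <- a[2:64, 2:64]
  expect_equal(sub, sub[rev(seq_len(63)), rev(seq_len(63))], tolerance = 1e-12)
  # phase difference centre -> radius r equals pi r^2 / (lambda u)
  k <- 6L
  r <- k * 10e-6
  dphi <- Arg(a[33, 33 + k] * Conj(a[33, 33]))
  expect_equal(dphi, pi * r^2 / (530e-9 * 0.1), tolerance = 1e-6)
  # doubling the depth halves the curvature
  f2 <- point_source_to_mask(cfg, source_depth = 0.2)
  dphi2 <- Arg(f2$amplitude[33, 33 + k] * Conj(f2$amplitude[33, 33]))
  expect_equal(dphi2, dphi / 2, tolerance = 1e-6)
})

test_that("single-pinhole PSF matches a direct Fresnel quadrature oracle", {
  cfg <- optical_config(0.05, 0.05, 530e-9, c(64, 64), 20e-6)
  d <- 2e-4
  mask <- pinhole_array(matrix(c(0, 0), 1), diameter = d, extent = c(6e-4, 6e-4))
  psf <- simulate_psf(cfg, mask)
  # independent brute-force Fresnel integral over the aperture
  ap_pitch <- 4e-6
  na <- ceiling(d / ap_pitch) + 2
  ay <- (seq_len(na) - (na %/% 2 + 1)) * ap_pitch
  open <- outer(ay^2, ay^2, `+`) <= (d / 2)^2
  ys <- rep(ay, times = na)[open]; xs <- rep(ay, each = na)[open]
  k <- 2 * pi / cfg$wavelength
  oracle <- function(x, y) {
    ph <- k * (xs^2 + ys^2) / (2 * cfg$u) +
          k * ((x - xs)^2 + (y - ys)^2) / (2 * cfg$v)
    Mod(sum(exp(1i * ph)))^2
  }
  ctr <- 33L
  sample_px <- c(0L, 2L, 4L, 6L)   # inside the main diffraction lobe
  sim <- psf$values[ctr, ctr + sample_px]
  ora <- vapply(sample_px * cfg$pixel_pitch, function(x) oracle(x, 0), numeric(1))
  # compare profiles up to a common scale
  expect_equal(sim / sim[1], ora / ora[1], tolerance = 0.05)
})

test_that("a lateral source shift moves the pattern by -(v/u) shift, sub-pixel", {
  dx <- -2.5 * cfg256$pixel_pitch * cfg256$u / cfg256$v
  psf2 <- simulate_psf(cfg256, mask100, source_xy = c(dx, 0))
  cc <- ncc_peak(psf256, psf2, subpixel = TRUE)
  expect_gt(cc$peak, 0.9)
  expect_equal(cc$shift[2], 2.5, tolerance = 0.3)
  expect_equal(cc$shift[1], 0, tolerance = 0.3)
})

test_that("a two-pinhole mask produces cosine fringes of period lambda v / d", {
  cfg <- optical_config(0.05, 0.05, 530e-9, c(256, 256), 10e-6)
  sep <- 4e-4
  mask <- pinhole_array(rbind(c(-sep / 2, 0), c(sep / 2, 0)),
                        diameter = 6e-5, extent = c(1e-3, 1e-3))
  psf <- simulate_psf(cfg, mask)
  row <- psf$values[129, ] - mean(psf$values[129, ])
  spec <- Mod(stats::fft(row))[1:128]
  # the fringe line sits well above the single-pinhole envelope band
  bins <- 15:100
  f_peak <- bins[which.max(spec[bins + 1])] / (256 * cfg$pixel_pitch)
  f_expected <- sep / (cfg$wavelength * cfg$v)
  expect_equal(f_peak, f_expected, tolerance = 0.05)
})

test_that("object frames are incoherent sums: single emitter and exact linearity", {
  e1 <- data.frame(x = 0, y = 0, z = cfg256$u, wavelength = cfg256$wavelength,
                   intensity = 1)
  io1 <- simulate_object_intensity(cfg256, mask100, scene_spec(emitters = e1))
  expect_equal(io1$values, psf256$values, tolerance = 1e-12)
  e2 <- data.frame(x = c(0, 3e-4), y = c(0, -2e-4), z = cfg256$u,
                   wavelength = cfg256$wavelength, intensity = c(1, 0.5))
  io_ab <- simulate_object_intensity(cfg256, mask100, scene_spec(emitters = e2))
  io_b <- simulate_object_intensity(cfg256, mask100, scene_spec(emitters = e2[2, ]))
  expect_equal(io_ab$values, io1$values + io_b$values, tolerance = 1e-12)
  expect_error(scene_spec(), "at least one")
})

test_that("convolution fast path matches emitter-by-emitter summation", {
  # small planar object, magnified pixels landing on the sensor lattice
  cfg <- optical_config(0.05, 0.05, 530e-9, c(128, 128), 12e-6)
  mask <- generate_rap(40, c(1e-3, 1e-3), 80e-6, seed = 3)
  bm <- matrix(0, 9, 9); bm[5, c(3, 5, 7)] <- 1; bm[3, 5] <- 0.5
  plane <- list(bitmap = bm, pitch = 3 * cfg$pixel_pitch * cfg$u / cfg$v,
                z = cfg$u, wavelength = cfg$wavelength, intensity = 1)
  sc <- scene_spec(planes = list(plane))
  io_conv <- simulate_object_intensity(cfg, mask, sc, method = "convolution")
  io_pts <- simulate_object_intensity(cfg, mask, sc, method = "points")
  rms <- sqrt(mean((io_conv$values - io_pts$values)^2)) /
    sqrt(mean(io_pts$values^2))
  expect_lt(rms, 0.02)
})

test_that("axial response curve is 1 at focus, bounded, and decays monotonically", {
  du <- seq(-0.015, 0.015, by = 0.0025)
  curve <- axial_response_curve(cfg256, mask100, du)
  expect_identical(curve$peak[du == 0], 1)
  expect_true(all(curve$peak >= 0 & curve$peak <= 1))
  # monotone decay beyond the first half-width on the smoothed curve
  sm <- stats::filter(curve$peak, rep(1 / 3, 3))
  right <- sm[which(du == 0):length(du)]
  right <- right[!is.na(right)]
  past_half <- right[right < 0.5]
  expect_true(all(diff(past_half) <= 1e-6))
  expect_error(axial_response_curve(cfg256, mask100, c(-0.01, 0.01)), "include 0")
})

test_that("spectral response peaks at the reference and is near-symmetric", {
  lams <- cfg256$wavelength * (1 + c(-0.05, -0.025, 0, 0.025, 0.05))
  sp <- spectral_response_curve(cfg256, mask100, lams)
  expect_identical(sp$peak[3], 1)
  expect_true(all(sp$peak <= 1))
  # symmetric within 20% for small fractional detuning
  expect_lt(abs(sp$peak[2] - sp$peak[4]) / max(sp$peak[c(2, 4)]), 0.2)
})

test_that("smaller pinholes give narrower axial and spectral correlation widths", {
  cfg <- optical_config(0.02, 0.02, 530e-9, c(128, 128), 10e-6, grid_oversample = 2L)
  m_big <- generate_rap(12, c(1e-3, 1e-3), 100e-6, seed = 3)
  m_small <- generate_rap(300, c(1e-3, 1e-3), 20e-6, seed = 4)
  lams <- 530e-9 * (1 + seq(-0.2, 0.2, by = 0.1))
  s_big <- spectral_response_curve(cfg, m_big, lams)
  s_small <- spectral_response_curve(cfg, m_small, lams)
  tails <- function(s) mean(s$peak[abs(lams / 530e-9 - 1) > 0.15])
  expect_lt(tails(s_small), tails(s_big))
})

test_that("oversized masks are rejected", {
  big <- generate_rap(10, c(5e-3, 5e-3), 100e-6, seed = 1)
  expect_error(simulate_psf(cfg256, big), "exceeds the simulation grid")
})
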