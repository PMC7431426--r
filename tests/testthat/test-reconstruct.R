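test_that("matched filter equals the brute-force circular correlation sum", {
  set.seed(101)
  a <- matrix(runif(16 * 16), 16)
  b <- matrix(runif(16 * 16), 16)
  r <- cross_correlate(a, b, "matched", pad = FALSE)$values
  a0 <- a - mean(a); b0 <- b - mean(b)
  brute <- matrix(0, 16, 16)
  for (dr in 0:15) for (dc in 0:15) {
    s <- 0
    for (i in 1:16) for (j in 1:16) {
      s <- s + a0[(i - 1 + dr) %% 16 + 1, (j - 1 + dc) %% 16 + 1] * b0[i, j]
    }
    brute[(dr + 8) %% 16 + 1, (dc + 8) %% 16 + 1] <- abs(s)
  }
  expect_lt(max(abs(r - brute)), 1e-9)
})

test_that("autocorrelation peaks at zero shift; shifted inputs move the peak", {
  v <- psf256$values
  r <- cross_correlate(v, v, "matched")
  expect_identical(arrayInd(which.max(r$values), dim(r$values)), cbind(129L, 129L))
  sh <- circshift(v, 7, -11)
  r2 <- nonlinear_correlation(sh, v, 0, 0.6, pad = FALSE)
  expect_identical(arrayInd(which.max(r2$values), dim(r2$values)),
                   cbind(129L + 7L, 129L - 11L))
  expect_error(cross_correlate(v, v[1:128, 1:128]), "identical shapes")
})

test_that("nonlinear correlation reduces exactly to matched and phase-only filters", {
  io <- psf256$values + 0.4 * circshift(psf256$values, 5, 9)
  for (pad in c(TRUE, FALSE)) {
    m <- cross_correlate(io, psf256$values, "matched", pad = pad)$values
    expect_lt(max(abs(m - nonlinear_correlation(io, psf256$values, 1, 1,
                                                pad = pad)$values)) / max(m), 1e-12)
    p <- cross_correlate(io, psf256$values, "phase_only", pad = pad)$values
    expect_lt(max(abs(p - nonlinear_correlation(io, psf256$values, 0, 1,
                                                pad = pad)$values)) / max(p), 1e-12)
  }
})

test_that("shift equivariance holds to floating precision (circular convention)", {
  v <- psf256$values
  io <- v + 0.3 * circshift(v, 3, 4)
  r0 <- nonlinear_correlation(io, v, 0, 0.6, pad = FALSE)$values
  r1 <- nonlinear_correlation(circshift(io, 5, -7), v, 0, 0.6, pad = FALSE)$values
  expect_lt(max(abs(r1 - circshift(r0, 5, -7))) / max(r0), 1e-12)
  expect_identical(arrayInd(which.max(r1), dim(r1)),
                   arrayInd(which.max(circshift(r0, 5, -7)), dim(r0)))
})

test_that("with both exponents zero the peak is invariant to intensity rescaling", {
  io <- psf256$values + 0.4 * circshift(psf256$values, 5, 9)
  r1 <- nonlinear_correlation(io, psf256$values, 0, 0, pad = FALSE)$values
  r2 <- nonlinear_correlation(7.3 * io, 2.1 * psf256$values, 0, 0, pad = FALSE)$values
  expect_equal(max(r1), max(r2), tolerance = 1e-9)
  expect_identical(arrayInd(which.max(r1), dim(r1)), arrayInd(which.max(r2), dim(r2)))
})

test_that("entropy matches hand-computed values and its bounds", {
  u <- matrix(1, 8, 8)
  expect_equal(recon_entropy(u, window = 8), log(64), tolerance = 1e-12)
  d <- matrix(0, 8, 8); d[3, 5] <- 2
  expect_equal(recon_entropy(d, window = 8), 0)
  two <- matrix(0, 4, 4); two[2, 2] <- 0.75; two[2, 3] <- 0.25
  expect_equal(recon_entropy(two, window = 4),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(recon_entropy(two, window = 4), 0.5623, tolerance = 1e-4)
  expect_error(recon_entropy(matrix(0, 8, 8), window = 4), "all-zero")
  set.seed(7)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32), 32)
    s <- recon_entropy(img, window = 16)
    expect_gte(s, 0); expect_lte(s, log(16 * 16))
  }
})

test_that("entropy search returns the grid argmin with deterministic tie-breaks", {
  io <- psf256$values + 0.5 * circshift(psf256$values, 10, 4)
  single <- search_filter_params(io, psf256$values, alpha_grid = 0.2,
                                 beta_grid = 0.7)
  expect_equal(single$alpha, 0.2); expect_equal(single$beta, 0.7)
  got <- search_filter_params(io, psf256$values, alpha_grid = 0,
                              beta_grid = seq(0.4, 1, by = 0.2))
  for (b in seq(0.4, 1, by = 0.2)) {
    s <- recon_entropy(nonlinear_correlation(io, psf256$values, 0, b))
    expect_lte(attr(got, "entropy"), s + 1e-12)
  }
  # the selected exponents beat the matched filter on point-object SNR
  snr_nl <- peak_snr(nonlinear_correlation(io, psf256$values, got$alpha, got$beta))
  snr_m <- peak_snr(cross_correlate(io, psf256$values, "matched"))
  expect_gte(snr_nl, snr_m)
})

test_that("low-pass and median stages have exact neutral settings", {
  img <- psf256$values
  expect_equal(lowpass_filter(img, 1), img, tolerance = 1e-12)
  low <- lowpass_filter(img, 0.2)
  expect_lt(stats::sd(low - mean(low)), stats::sd(img - mean(img)))
  expect_identical(median_filter(img, 1), img)
  spike <- matrix(1, 16, 16); spike[8, 8] <- 100
  expect_equal(median_filter(spike, 3), matrix(1, 16, 16), tolerance = 1e-9)
  expect_error(filter_params(median_kernel = 4), "median_kernel")
})

test_that("the spectrum-domain filter is neutral at zero strength and suppresses noise", {
  v <- psf256$values
  expect_identical(spectrum_domain_filter(v, v, 0), v)
  # identical frames: agreement ~ 1, reconstruction essentially unchanged
  same <- spectrum_domain_filter(v, v, 1)
  r_f <- nonlinear_correlation(same, v, 0, 0.6)$values
  r_0 <- nonlinear_correlation(v, v, 0, 0.6)$values
  expect_gt(max(r_f) / max(r_0), 0.5)
  # pure white-noise object against a structured PSF: background drops
  set.seed(21)
  noise <- matrix(runif(256 * 256), 256)
  rn0 <- nonlinear_correlation(noise, v, 0, 1)$values
  rnf <- nonlinear_correlation(spectrum_domain_filter(noise, v, 1), v, 0, 1)$values
  expect_lt(stats::var(as.vector(rnf / max(rnf))),
            stats::var(as.vector(rn0 / max(rn0))))
})

test_that("the pipeline with neutral stages and (1,1) is the matched filter", {
  io <- psf256$values + 0.4 * circshift(psf256$values, 5, 9)
  r <- reconstruct_pipeline(io, psf256$values,
                            filter_params(alpha = 1, beta = 1))$values
  m <- cross_correlate(io, psf256$values, "matched")$values
  expect_lt(max(abs(r - m)) / max(m), 1e-12)
})

test_that("correct-depth PSF beats a defocused PSF on a two-plane scene", {
  # plane separation half the axial FWHM (~1.06 cm for this geometry)
  du_half <- 0.005
  psf_wrong <- simulate_psf(cfg256, mask100, source_depth = cfg256$u + du_half)
  e <- data.frame(x = c(0, 4e-4), y = 0, z = c(cfg256$u, cfg256$u + du_half),
                  wavelength = cfg256$wavelength, intensity = 1)
  io <- simulate_object_intensity(cfg256, mask100, scene_spec(emitters = e[1, ]))
  snr_right <- peak_snr(reconstruct_pipeline(io, psf256, filter_params()))
  snr_wrong <- peak_snr(reconstruct_pipeline(io, psf_wrong, filter_params()))
  expect_gt(snr_right, snr_wrong)
})

test_that("autocorrelation of an optimized-scale QRAP is delta-like (SNR >= 20)", {
  cfg <- optical_config(0.1, 0.1, 530e-9, c(512, 512), 16e-6, grid_oversample = 2L)
  mask <- generate_rap(2000, c(8e-3, 8e-3), 80e-6, seed = 9)
  psf <- suppressWarnings(simulate_psf(cfg, mask))
  lam <- nonlinear_correlation(psf, psf, 0, 0.6)
  expect_gte(peak_snr(lam, exclusion_radius = 8), 20)
})
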