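# Shared small geometries and fixtures. Everything is generated in code; the
# characterization geometry (256^2 sensor at 12 um, 2 mm mask of 100 x 80 um
# pinholes, u = v = 10 cm, 530 nm) keeps one Fresnel propagation around 50 ms.

cfg256 <- optical_config(u = 0.1, v = 0.1, wavelength = 530e-9,
                         sensor_shape = c(256, 256), pixel_pitch = 12e-6)

mask100 <- generate_rap(100, extent = c(2e-3, 2e-3), diameter = 80e-6, seed = 11)

psf256 <- simulate_psf(cfg256, mask100)

# tiny geometry for optimization loops (u chosen so the source curvature
# stays resolved over a 1 mm mask on the coarse grid)
cfg64 <- optical_config(u = 0.08, v = 0.08, wavelength = 530e-9,
                        sensor_shape = c(64, 64), pixel_pitch = 20e-6)

gaussian_field <- function(n = 128, pitch = 10e-6, w = 80e-6, lam = 530e-9) {
  y <- (seq_len(n) - (n %/% 2 + 1)) * pitch
  r2 <- outer(y^2, y^2, `+`)
  complex_field(matrix(complex(real = exp(-r2 / (2 * w^2))), n), pitch, lam)
}

# anti-aliased circular aperture field (plane-wave illumination)
disc_field <- function(n, pitch, radius, lam) {
  y <- (seq_len(n) - (n %/% 2 + 1)) * pitch
  r <- sqrt(outer(y^2, y^2, `+`))
  edge <- pmin(pmax((radius - r) / pitch + 0.5, 0), 1)
  complex_field(matrix(complex(real = edge), n), pitch, lam)
}

circshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

fwhm_of_curve <- function(x, y) {
  f <- stats::approxfun(x, y - 0.5)
  lo <- stats::uniroot(f, c(min(x), 0))$root
  hi <- stats::uniroot(f, c(0, max(x)))$root
  hi - lo
}
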