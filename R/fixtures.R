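# Synthetic test objects and sensor effects: everything needed to exercise the
# full imaging pipeline without any recorded data.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Resolution-target and scene-object specification
#'
#' Describes one of the standard synthetic test objects: a three-bar
#' resolution element at a given spatial frequency (the USAF/NBS style bar
#' groups), a crosshair, a grid of points, or an arbitrary bitmap.
#'
#' @param kind One of `"three_bar"`, `"crosshair"`, `"point_grid"`,
#'   `"bitmap"`.
#' @param lp_per_mm Spatial frequency in line pairs per mm (bar targets).
#' @param extent Physical side length of the rendered object in metres.
#' @param polarity `"positive"` (bright features on dark) or `"negative"`.
#' @param linewidth Line width in metres (crosshair).
#' @param n Points per side (point grid).
#' @param bitmap Non-negative matrix (kind `"bitmap"`).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(kind = c("three_bar", "crosshair", "point_grid", "bitmap"),
                        lp_per_mm = NULL, extent = 1e-3,
                        polarity = c("positive", "negative"),
                        linewidth = NULL, n = 3L, bitmap = NULL) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  if (kind == "three_bar" && (is.null(lp_per_mm) || lp_per_mm <= 0))
    stop("bar targets need a positive spatial frequency")
  stopifnot(extent > 0)
  structure(list(kind = kind, lp_per_mm = lp_per_mm, extent = extent,
                 polarity = polarity, linewidth = linewidth, n = n,
                 bitmap = bitmap),
            class = "target_spec")
}

#' Render a standard three-bar resolution element
#'
#' Three parallel bars at the stated spatial frequency (bar width = half the
#' line-pair period, bar length 2.5 periods), centred in a square canvas. An
#' 8 lp/mm element has a 125 um period.
#'
#' @param lp_per_mm Spatial frequency in line pairs per mm.
#' @param extent Canvas side in metres.
#' @param pitch Render pitch in metres; must resolve the period by at least 4
#'   samples.
#' @param polarity `"positive"` or `"negative"`.
#' @return A matrix with values in `{0, 1}`.
#' @export
make_bar_target <- function(lp_per_mm, extent, pitch,
                            polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(lp_per_mm > 0, extent > 0)
  period <- 1e-3 / lp_per_mm
  if (pitch > period / 4)
    stop(sprintf("pitch %g um under-resolves the %g um bar period (need >= 4 samples)",
                 pitch * 1e6, period * 1e6))
  n <- max(16L, round(extent / pitch))
  x <- grid_coords(n, pitch); y <- grid_coords(n, pitch)
  w <- period / 2
  bar_centres <- c(-period, 0, period)
  in_bar_x <- vapply(x, function(xx) any(abs(xx - bar_centres) <= w / 2), logical(1))
  in_bar_y <- abs(y) <= 2.5 * period / 2
  img <- outer(in_bar_y, in_bar_x, `&`) * 1
  if (polarity == "negative") img <- 1 - img
  img
}

render_crosshair <- function(extent, pitch, linewidth) {
  n <- max(16L, round(extent / pitch))
  x <- grid_coords(n, pitch); y <- grid_coords(n, pitch)
  arm <- extent / 2.5
  img <- outer(abs(y) <= linewidth / 2, abs(x) <= arm, `&`) |
         outer(abs(y) <= arm, abs(x) <= linewidth / 2, `&`)
  img * 1
}

render_point_grid <- function(extent, pitch, n_points) {
  n <- max(16L, round(extent / pitch))
  img <- matrix(0, n, n)
  pos <- round(seq(0.2, 0.8, length.out = n_points) * (n - 1)) + 1L
  img[pos, pos] <- 1
  img
}

#' Render a target specification to a bitmap
#'
#' @param spec A [target_spec].
#' @param pitch Render pitch in metres.
#' @return A non-negative matrix.
#' @export
render_target <- function(spec, pitch) {
  stopifnot(inherits(spec, "target_spec"))
  img <- switch(spec$kind,
    three_bar = make_bar_target(spec$lp_per_mm, spec$extent, pitch, spec$polarity),
    crosshair = {
      img <- render_crosshair(spec$extent, pitch,
                              spec$linewidth %||% (spec$extent / 20))
      if (spec$polarity == "negative") 1 - img else img
    },
    point_grid = render_point_grid(spec$extent, pitch, spec$n),
    bitmap = spec$bitmap)
  if (spec$kind == "bitmap" && spec$polarity == "negative") img <- max(img) - img
  img
}

#' Build a multi-plane, multi-wavelength scene from target objects
#'
#' Renders each object and places it at its depth and wavelength as a planar
#' incoherent source, producing the [scene_spec] consumed by
#' [simulate_object_intensity()].
#'
#' @param objects List of entries, each a list with `target` (a [target_spec]
#'   or a bitmap matrix), `z` (metres), `wavelength` (metres), optional
#'   `intensity` (default 1) and `pitch` (object-plane metres/pixel; required
#'   for bitmap matrices, defaulted to `extent/64` for specs).
#' @return A [scene_spec] with one plane per object.
#' @export
make_scene <- function(objects) {
  stopifnot(length(objects) >= 1)
  planes <- lapply(objects, function(ob) {
    tg <- ob$target
    if (inherits(tg, "target_spec")) {
      pitch <- ob$pitch %||% (tg$extent / 64)
      bitmap <- render_target(tg, pitch)
    } else {
      if (is.null(ob$pitch)) stop("bitmap objects need an explicit pitch")
      pitch <- ob$pitch
      bitmap <- tg
    }
    list(bitmap = bitmap, pitch = pitch, z = ob$z, wavelength = ob$wavelength,
         intensity = ob$intensity %||% 1)
  })
  scene_spec(planes = planes)
}

#' Sample an LED spectrum as weighted monochromatic lines
#'
#' Approximates a polychromatic LED (Gaussian line shape of the stated FWHM)
#' by a small set of equally spaced monochromatic lines with Gaussian
#' weights, normalized to unit total. Attaching these wavelengths and weights
#' to otherwise identical emitters in a [scene_spec] simulates broadband
#' illumination by incoherent intensity addition, e.g. the 530 nm / 33 nm
#' FWHM source class used for recording.
#'
#' @param center Centre wavelength in metres.
#' @param fwhm Full width at half maximum in metres.
#' @param n Number of lines (odd keeps the centre line; default 7).
#' @param span Sampled range in units of FWHM (default +/- 1 FWHM).
#' @return data.frame with columns `wavelength` and `weight` (summing to 1).
#' @examples
#' led_lines(530e-9, 33e-9)
#' @export
led_lines <- function(center, fwhm, n = 7L, span = 1) {
  stopifnot(center > 0, fwhm > 0, n >= 1)
  if (n == 1L) return(data.frame(wavelength = center, weight = 1))
  lam <- seq(center - span * fwhm, center + span * fwhm, length.out = n)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(lam - center)^2 / (2 * sigma^2))
  data.frame(wavelength = lam, weight = w / sum(w))
}

#' Apply a sensor noise / quantization model to a frame
#'
#' Seeded, reproducible sensor effects: `"poisson"` draws photon shot noise
#' with `photon_scale` expected photons per unit intensity, `"gaussian"` adds
#' read noise of standard deviation `sigma` (clamped at zero), and
#' `"quantize"` rounds to `2^bits` levels over the frame's range.
#'
#' @param i An [intensity_pattern] or matrix.
#' @param model `"poisson"`, `"gaussian"` or `"quantize"`.
#' @param photon_scale Photons per intensity unit (> 0).
#' @param sigma Gaussian noise standard deviation (intensity units).
#' @param bits 8 or 16.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Same type as the input, non-negative.
#' @export
add_noise <- function(i, model = c("poisson", "gaussian", "quantize"),
                      photon_scale = 1e4, sigma = 0.01, bits = 16L,
                      seed = NULL) {
  model <- match.arg(model)
  v <- as_values(i)
  out <- with_seed(seed, switch(model,
    poisson = {
      stopifnot(photon_scale > 0)
      matrix(stats::rpois(length(v), v * photon_scale) / photon_scale, nrow(v))
    },
    gaussian = pmax(v + matrix(stats::rnorm(length(v), sd = sigma), nrow(v)), 0),
    quantize = {
      if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
      mx <- max(v)
      if (mx == 0) v else round(v / mx * (2^bits - 1)) / (2^bits - 1) * mx
    }))
  if (is.matrix(i)) return(out)
  i$values <- out
  i
}

#' Block all but a central region of the sensor
#'
#' Emulates the partial-sensor experiment: pixels outside the central
#' `fraction` of each axis are zeroed (the shape is preserved). With
#' `fraction = 1/3`, about 1/9 of the pixel area stays active.
#'
#' @param i An [intensity_pattern] or matrix.
#' @param fraction Active central fraction per linear axis, in `(0, 1]`.
#' @param region Only `"center"` is supported.
#' @return Same type as the input.
#' @export
crop_sensor <- function(i, fraction, region = "center") {
  stopifnot(fraction > 0, fraction <= 1, region == "center")
  v <- as_values(i)
  if (fraction == 1) return(i)
  keep <- function(n) {
    m <- round(n * fraction)
    a <- (n - m) %/% 2L
    seq.int(a + 1L, a + m)
  }
  out <- matrix(0, nrow(v), ncol(v))
  r <- keep(nrow(v)); c <- keep(ncol(v))
  out[r, c] <- v[r, c]
  if (is.matrix(i)) return(out)
  i$values <- out
  i
}
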