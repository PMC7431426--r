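#' Optical geometry and sensor description
#'
#' Bundles the imaging geometry of the lensless pinhole-array camera: a point
#' source (or object plane) at distance `u` in front of the mask, the sensor at
#' distance `v` behind it, a design wavelength, and the sensor sampling. All
#' quantities are SI (metres); the on-disk YAML interface uses mm/nm/um, see
#' [read_optical_config()].
#'
#' @param u Source(object)-plane to mask distance in metres (> 0).
#' @param v Mask to sensor distance in metres (> 0).
#' @param wavelength Design wavelength in metres (> 0).
#' @param sensor_shape Integer `(rows, cols)` of the sensor, each >= 16.
#' @param pixel_pitch Sensor pixel pitch in metres/pixel (> 0).
#' @param grid_oversample Positive integer; the simulation grid refines the
#'   sensor grid by this factor (simulation pitch = `pixel_pitch /
#'   grid_oversample`), and simulated intensities are box-averaged back onto
#'   sensor pixels.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(u = 0.1, v = 0.1, wavelength = 530e-9,
#'                       sensor_shape = c(256, 256), pixel_pitch = 12e-6)
#' @export
optical_config <- function(u, v, wavelength, sensor_shape = c(512L, 512L),
                           pixel_pitch = 16e-6, grid_oversample = 1L) {
  stopifnot(u > 0, v > 0, wavelength > 0, pixel_pitch > 0)
  sensor_shape <- as.integer(sensor_shape)
  grid_oversample <- as.integer(grid_oversample)
  if (length(sensor_shape) != 2L || any(sensor_shape < 16L))
    stop("sensor_shape must be two integers >= 16")
  if (grid_oversample < 1L) stop("grid_oversample must be >= 1")
  structure(list(u = u, v = v, wavelength = wavelength,
                 sensor_shape = sensor_shape, pixel_pitch = pixel_pitch,
                 grid_oversample = grid_oversample),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> u = %g mm, v = %g mm, lambda = %g nm\n",
              x$u * 1e3, x$v * 1e3, x$wavelength * 1e9))
  cat(sprintf("  sensor %d x %d px @ %g um, oversample %d\n",
              x$sensor_shape[1], x$sensor_shape[2], x$pixel_pitch * 1e6,
              x$grid_oversample))
  invisible(x)
}

sim_grid <- function(config) {
  list(shape = config$sensor_shape * config$grid_oversample,
       pitch = config$pixel_pitch / config$grid_oversample)
}

#' Sampled complex optical field
#'
#' A rectangular grid of complex amplitudes with its sample pitch and
#' wavelength. Fields are the working representation of the propagating
#' chaotic wave between the mask and the sensor.
#'
#' @param amplitude Complex (or real, promoted) matrix of samples.
#' @param pitch Metres per sample (> 0).
#' @param wavelength Wavelength in metres (> 0).
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(amplitude, pitch, wavelength) {
  stopifnot(is.matrix(amplitude), pitch > 0, wavelength > 0)
  if (!is.complex(amplitude)) storage.mode(amplitude) <- "complex"
  if (any(!is.finite(Re(amplitude))) || any(!is.finite(Im(amplitude))))
    stop("field amplitude must be finite")
  structure(list(amplitude = amplitude, pitch = pitch, wavelength = wavelength),
            class = "complex_field")
}

#' Total energy carried by a field
#'
#' Sum of squared magnitudes times the sample area. Conserved by free-space
#' propagation ([fresnel_propagate()]) to numerical precision in the
#' transfer-function form.
#' @param field A [complex_field].
#' @return Scalar energy (arbitrary units x m^2).
#' @export
field_energy <- function(field) {
  sum(Mod(field$amplitude)^2) * field$pitch^2
}

#' Largest distance valid for the transfer-function Fresnel propagator
#'
#' The frequency-space Fresnel kernel is adequately sampled on an `n`-sample
#' grid of pitch `p` only for propagation distances `|d| <= n * p^2 / lambda`
#' (including the zero padding applied before the transform). Beyond that the
#' single-transform impulse-response form must be used instead.
#'
#' @param field A [complex_field].
#' @param pad_factor Zero-padding factor applied before the FFT (default 2).
#' @return Maximum |distance| in metres for the transfer-function form.
#' @export
max_transfer_distance <- function(field, pad_factor = 2) {
  n <- min(dim(field$amplitude)) * pad_factor
  n * field$pitch^2 / field$wavelength
}

#' Fresnel (paraxial) free-space propagation
#'
#' Propagates a sampled complex field by `distance` using scalar diffraction in
#' the Fresnel approximation. Two standard forms are provided: the
#' transfer-function form (Fresnel kernel applied in frequency space; preserves
#' grid shape and pitch, exactly energy conserving, valid for `|distance| <=`
#' [max_transfer_distance()]) and the single-transform impulse-response form
#' (valid for long distances; the output pitch becomes
#' `lambda * |distance| / (n * pitch)`). `method = "auto"` picks the
#' transfer-function form whenever its sampling criterion holds.
#'
#' Propagation by `+d` followed by `-d` in the transfer-function form is an
#' exact inverse.
#'
#' @param field A [complex_field].
#' @param distance Signed propagation distance in metres (non-zero).
#' @param method `"auto"`, `"transfer"` or `"impulse"`.
#' @param pad_factor Linear zero-padding factor (>= 1; default 2) used to
#'   suppress wrap-around in the transfer-function form.
#' @return A [complex_field] at the new plane.
#' @export
fresnel_propagate <- function(field, distance,
                              method = c("auto", "transfer", "impulse"),
                              pad_factor = 2) {
  method <- match.arg(method)
  stopifnot(inherits(field, "complex_field"))
  if (distance == 0) stop("distance must be non-zero")
  dmax <- max_transfer_distance(field, pad_factor)
  if (method == "auto") method <- if (abs(distance) <= dmax) "transfer" else "impulse"
  if (method == "transfer") {
    if (abs(distance) > dmax)
      stop(sprintf(paste0("transfer-function propagator undersampled for |distance| = %g m; ",
                          "maximum valid distance for this grid is %g m ",
                          "(use method = \"impulse\" or a coarser/larger grid)"),
                   abs(distance), dmax))
    padded <- propagate_padded(field$amplitude, field$pitch, field$wavelength,
                               distance, pad_factor)
    out <- crop_centre(padded, dim(field$amplitude))
    return(complex_field(out, field$pitch, field$wavelength))
  }
  # impulse-response (single transform) form
  amp <- field$amplitude
  shape <- dim(amp) * ceiling(pad_factor)
  amp <- pad_centre(amp, shape)
  n <- dim(amp)
  lam <- field$wavelength
  p1 <- field$pitch
  y1 <- grid_coords(n[1], p1); x1 <- grid_coords(n[2], p1)
  q1 <- exp(1i * pi / (lam * distance) * outer(y1^2, x1^2, `+`))
  f <- amp * q1
  f <- ifftshift(f)
  tf <- if (distance > 0) stats::fft(f) else stats::fft(f, inverse = TRUE) / length(f)
  tf <- fftshift(tf)
  p2 <- lam * abs(distance) / (n[1] * p1)  # square grids assumed for this form
  if (n[1] != n[2]) stop("impulse-response form requires a square grid")
  y2 <- grid_coords(n[1], p2); x2 <- grid_coords(n[2], p2)
  q2 <- exp(1i * pi / (lam * distance) * outer(y2^2, x2^2, `+`))
  pref <- exp(2i * pi * distance / lam) / (1i * lam * distance) * p1^2
  complex_field(pref * q2 * tf, p2, lam)
}

propagate_padded <- function(amp, pitch, lam, distance, pad_factor = 2) {
  shape <- dim(amp) * ceiling(pad_factor)
  u <- pad_centre(amp, shape)
  fy <- fft_freqs(shape[1], pitch); fx <- fft_freqs(shape[2], pitch)
  h <- exp(2i * pi * distance / lam) *
    exp(-1i * pi * lam * distance * outer(fy^2, fx^2, `+`))
  fftshift(ifft2(stats::fft(ifftshift(u)) * h))
}

#' Paraxial spherical wave from a point source at the mask plane
#'
#' Returns the quadratic-phase (paraxial) approximation of the diverging
#' spherical wave emitted by a point source at transverse position `source_xy`
#' and distance `source_depth` in front of the mask, sampled on the simulation
#' grid of `config`.
#'
#' @param config An [optical_config].
#' @param source_xy Numeric `(x, y)` source position in metres.
#' @param source_depth Source to mask distance in metres (> 0); defaults to
#'   `config$u`.
#' @return A [complex_field] at the mask plane (unit amplitude).
#' @export
point_source_to_mask <- function(config, source_xy = c(0, 0),
                                 source_depth = config$u) {
  stopifnot(inherits(config, "optical_config"), source_depth > 0)
  g <- sim_grid(config)
  k <- 2 * pi / config$wavelength
  y <- grid_coords(g$shape[1], g$pitch) - source_xy[2]
  x <- grid_coords(g$shape[2], g$pitch) - source_xy[1]
  amp <- exp(1i * k / (2 * source_depth) * outer(y^2, x^2, `+`))
  complex_field(amp, g$pitch, config$wavelength)
}

mask_raster_for <- function(config, mask) {
  g <- sim_grid(config)
  if (is.matrix(mask)) {
    if (!all(dim(mask) == g$shape))
      stop("pre-rasterized mask must match the simulation grid shape")
    return(mask)
  }
  stopifnot(inherits(mask, "pinhole_array"))
  ext <- g$shape * g$pitch
  if (mask$extent[1] > ext[2] || mask$extent[2] > ext[1])
    stop(sprintf("mask extent (%g x %g mm) exceeds the simulation grid (%g x %g mm)",
                 mask$extent[1] * 1e3, mask$extent[2] * 1e3, ext[2] * 1e3, ext[1] * 1e3))
  raster <- rasterize_mask(mask, g$pitch, shape = g$shape)
  r <- mask$diameter / 2
  attr(raster, "max_radius") <- if (nrow(mask$centers))
    sqrt(max(mask$centers[, 1]^2 + mask$centers[, 2]^2)) + r else 0
  raster
}

#' Simulate the chaotic point spread intensity pattern of a pinhole-array mask
#'
#' Propagates the paraxial spherical wave of a point source through the mask
#' (multiplicative binary transmission) and onward to the sensor by Fresnel
#' diffraction, then records the squared magnitude, box-averaged onto sensor
#' pixels. This is the system PSF `I_PSF(z, lambda)` recorded during training.
#'
#' @param config An [optical_config] (its `wavelength` is used).
#' @param mask A [pinhole_array], or a binary matrix already rasterized on the
#'   simulation grid (useful to amortize rasterization over many calls).
#' @param source_xy Source transverse position `(x, y)` in metres.
#' @param source_depth Source distance in metres; defaults to `config$u`.
#' @param intensity Relative source intensity (multiplies the pattern).
#' @return An [intensity_pattern] with role `"psf"` and metadata
#'   `(z = source_depth, du = source_depth - config$u, wavelength)`.
#'
#' @details
#' The spherical source phase oscillates faster towards the mask edge and for
#' off-axis sources; when the local spatial frequency over the open mask area
#' would exceed the simulation grid's Nyquist limit for an off-axis source,
#' the source offset is factored out analytically instead: in the paraxial
#' model a lateral source shift translates the sensor pattern rigidly by
#' `-(v / source_depth) * source_xy`, so the on-axis pattern is simulated
#' (on a grid of twice the sensor extent, so content shifts in from beyond
#' the edges) and translated. If even the on-axis curvature is undersampled a
#' warning suggests a larger `grid_oversample`.
#' @export
simulate_psf <- function(config, mask, source_xy = c(0, 0),
                         source_depth = config$u, intensity = 1) {
  raster <- mask_raster_for(config, mask)
  g <- sim_grid(config)
  r_max <- raster_max_radius(raster, g$pitch)
  nyq <- 1 / (2 * g$pitch)
  lamz <- config$wavelength * source_depth
  off <- sqrt(sum(source_xy^2))
  direct_ok <- (r_max + off) / lamz <= nyq
  if (!direct_ok && r_max / lamz > nyq)
    warning("mask-edge curvature undersampled on the simulation grid; ",
            "increase grid_oversample for faithful outer-pinhole diffraction")
  if (direct_ok) {
    src <- point_source_to_mask(config, source_xy, source_depth)
    field <- complex_field(src$amplitude * raster, src$pitch, src$wavelength)
    out <- fresnel_propagate(field, config$v, method = "transfer")
    img <- Mod(out$amplitude)^2
  } else {
    # exact paraxial factoring: on-axis simulation + rigid pattern shift
    src <- point_source_to_mask(config, c(0, 0), source_depth)
    padded <- propagate_padded(src$amplitude * raster, g$pitch,
                               config$wavelength, config$v, 2)
    ext <- Mod(crop_centre(padded, 2L * g$shape))^2
    shift_px <- -(config$v / source_depth) * c(source_xy[2], source_xy[1]) / g$pitch
    img <- crop_centre(shift_bilinear(ext, shift_px[1], shift_px[2]), g$shape)
  }
  img <- box_downsample(img * intensity, config$grid_oversample)
  intensity_pattern(img, config$pixel_pitch, wavelength = config$wavelength,
                    z = source_depth, du = source_depth - config$u, role = "psf")
}

raster_max_radius <- function(raster, pitch) {
  cached <- attr(raster, "max_radius")
  if (!is.null(cached)) return(cached)
  idx <- which(raster > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  y <- grid_coords(nrow(raster), pitch)[idx[, 1]]
  x <- grid_coords(ncol(raster), pitch)[idx[, 2]]
  sqrt(max(x^2 + y^2))
}

# sample m at (row + dy, col + dx), bilinear, zero outside (exact for integer
# shifts)
shift_bilinear <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  if (dy == round(dy) && dx == round(dx)) {  # exact integer translation
    out <- matrix(0, nr, nc)
    sr <- seq_len(nr) - as.integer(round(dy)); sc <- seq_len(nc) - as.integer(round(dx))
    okr <- sr >= 1 & sr <= nr; okc <- sc >= 1 & sc <= nc
    out[okr, okc] <- m[sr[okr], sc[okc]]
    return(out)
  }
  # new(x) = old(x - shift): pattern content moves by +(dy, dx)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  valid_r <- r0 >= 1 & r0 <= nr - 1; valid_c <- c0 >= 1 & c0 <= nc - 1
  r0 <- pmin(pmax(r0, 1L), nr - 1L); c0 <- pmin(pmax(c0, 1L), nc - 1L)
  gather <- function(ri, ci) m[cbind(rep(ri, times = nc), rep(ci, each = nr))]
  out <- (1 - fr) %o% (1 - fc) * matrix(gather(r0, c0), nr) +
         fr %o% (1 - fc)       * matrix(gather(r0 + 1L, c0), nr) +
         (1 - fr) %o% fc       * matrix(gather(r0, c0 + 1L), nr) +
         fr %o% fc             * matrix(gather(r0 + 1L, c0 + 1L), nr)
  out[!valid_r, ] <- 0
  out[, !valid_c] <- 0
  out
}

# PSF intensity on a sensor-pitch grid twice the sensor extent (for the
# convolution fast path, so pattern content shifting in from beyond the sensor
# edge is retained).
simulate_psf_extended <- function(config, mask, source_depth = config$u) {
  raster <- mask_raster_for(config, mask)
  src <- point_source_to_mask(config, c(0, 0), source_depth)
  g <- sim_grid(config)
  padded <- propagate_padded(src$amplitude * raster, g$pitch, config$wavelength,
                             config$v, 2)
  img <- Mod(crop_centre(padded, 2L * g$shape))^2
  box_downsample(img, config$grid_oversample)
}

#' Non-negative intensity frame with optical metadata
#'
#' The camera-facing data type: a 2D grid of non-negative intensities plus the
#' pixel pitch and the `(z | du, wavelength)` coordinates it was recorded or
#' simulated at, with a role tag distinguishing point-spread recordings from
#' object frames.
#'
#' @param values Non-negative numeric matrix.
#' @param pitch Metres per pixel.
#' @param wavelength,z,du Optional metadata in metres (`du` is the axial offset
#'   from a reference object distance; positive means farther from the mask).
#' @param role `"psf"` or `"object"`.
#' @param scale Multiplicative factor mapping stored values to physical units
#'   (used by the 16-bit writers; 1 for in-memory patterns).
#' @return An object of class `intensity_pattern`.
#' @export
intensity_pattern <- function(values, pitch, wavelength = NA_real_,
                              z = NA_real_, du = NA_real_,
                              role = c("psf", "object"), scale = 1) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), pitch > 0)
  if (any(values < 0)) stop("intensity values must be non-negative")
  structure(list(values = values, pitch = pitch,
                 meta = list(wavelength = wavelength, z = z, du = du,
                             role = role, scale = scale)),
            class = "intensity_pattern")
}

#' @export
print.intensity_pattern <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<intensity_pattern:%s> %d x %d px @ %g um, lambda = %s nm, z = %s mm\n",
              m$role, nrow(x$values), ncol(x$values), x$pitch * 1e6,
              format(m$wavelength * 1e9), format(m$z * 1e3)))
  invisible(x)
}

#' Scene description: point emitters and planar objects
#'
#' A scene is a collection of mutually incoherent emitters - individual points
#' and/or planar bitmap objects - each with a depth, a wavelength and a
#' non-negative relative intensity. Intensities add at the sensor.
#'
#' @param emitters `NULL` or a data.frame with columns `x, y` (metres,
#'   transverse), `z` (metres, object-side depth from the mask), `wavelength`
#'   (metres) and `intensity` (>= 0).
#' @param planes `NULL` or a list of planar objects, each a list with elements
#'   `bitmap` (non-negative matrix of per-pixel source intensities), `pitch`
#'   (object-plane metres/pixel), `z`, `wavelength` and optional `intensity`
#'   scaling (default 1).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(emitters = NULL, planes = NULL) {
  if (is.null(emitters) && length(planes) == 0L)
    stop("scene must contain at least one emitter or planar object")
  if (!is.null(emitters)) {
    stopifnot(is.data.frame(emitters),
              all(c("x", "y", "z", "wavelength", "intensity") %in% names(emitters)))
    if (nrow(emitters) == 0L && length(planes) == 0L)
      stop("scene must contain at least one emitter or planar object")
    if (any(emitters$intensity < 0)) stop("emitter intensities must be >= 0")
    if (any(emitters$z <= 0) || any(emitters$wavelength <= 0))
      stop("emitter depths and wavelengths must be positive")
  }
  for (p in planes) {
    stopifnot(is.matrix(p$bitmap), p$pitch > 0, p$z > 0, p$wavelength > 0)
    if (any(p$bitmap < 0)) stop("plane bitmaps must be non-negative")
  }
  structure(list(emitters = emitters, planes = planes), class = "scene_spec")
}

#' Convert a planar bitmap object into point emitters
#'
#' Every strictly positive bitmap pixel becomes one point emitter at its pixel
#' centre. Used as the brute-force path that the convolution fast path is
#' checked against.
#'
#' @param plane One element of `scene_spec()$planes`.
#' @return A data.frame of emitters (see [scene_spec()]).
#' @export
plane_to_emitters <- function(plane) {
  b <- plane$bitmap
  idx <- which(b > 0, arr.ind = TRUE)
  y <- grid_coords(nrow(b), plane$pitch)[idx[, 1]]
  x <- grid_coords(ncol(b), plane$pitch)[idx[, 2]]
  data.frame(x = x, y = y, z = plane$z, wavelength = plane$wavelength,
             intensity = b[idx] * (plane$intensity %||% 1))
}

#' Simulate the single-shot object intensity frame of a scene
#'
#' Sums, in intensity, the chaotic pattern of every incoherent emitter in the
#' scene: the monochrome frame `I_O = sum_{i,j} O(lambda_i, z_j) (x)
#' I_PSF(lambda_i, z_j)` that the camera records in one shot. Point emitters
#' are simulated individually; planar bitmaps use a convolution fast path (the
#' object is magnified by `v/z`, inverted, and convolved with the on-axis PSF
#' simulated on an extended grid), unless `method = "points"` forces
#' emitter-by-emitter summation.
#'
#' @param config An [optical_config].
#' @param mask A [pinhole_array] or pre-rasterized matrix.
#' @param scene A [scene_spec].
#' @param method `"auto"` (convolution for planes, direct for emitters),
#'   `"points"` (everything emitter-by-emitter) or `"convolution"`.
#' @return An [intensity_pattern] with role `"object"`.
#' @export
simulate_object_intensity <- function(config, mask, scene,
                                      method = c("auto", "points", "convolution")) {
  method <- match.arg(method)
  stopifnot(inherits(scene, "scene_spec"))
  raster <- mask_raster_for(config, mask)
  acc <- matrix(0, config$sensor_shape[1], config$sensor_shape[2])
  emitters <- scene$emitters
  planes <- scene$planes
  if (method == "points" && length(planes)) {
    extra <- do.call(rbind, lapply(planes, plane_to_emitters))
    emitters <- rbind(emitters, extra)
    planes <- NULL
  }
  if (!is.null(emitters) && nrow(emitters)) {
    for (i in seq_len(nrow(emitters))) {
      e <- emitters[i, ]
      cfg <- config; cfg$wavelength <- e$wavelength
      p <- simulate_psf(cfg, raster, source_xy = c(e$x, e$y),
                        source_depth = e$z, intensity = e$intensity)
      acc <- acc + p$values
    }
  }
  for (p in planes) {
    cfg <- config; cfg$wavelength <- p$wavelength
    psf_ext <- simulate_psf_extended(cfg, raster, source_depth = p$z)
    obj_ext <- splat_object(p, config, dim(psf_ext))
    conv <- Re(stats::fft(stats::fft(obj_ext) * stats::fft(ifftshift(psf_ext)),
                          inverse = TRUE)) / length(obj_ext)
    acc <- acc + pmax(crop_centre(conv, config$sensor_shape), 0) * (p$intensity %||% 1)
  }
  intensity_pattern(acc, config$pixel_pitch, role = "object")
}

# Place the geometrically magnified, inverted object onto an extended
# sensor-pitch grid by bilinear splatting (conserves total intensity).
splat_object <- function(plane, config, shape) {
  m <- config$v / plane$z
  b <- plane$bitmap
  idx <- which(b > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, shape[1], shape[2]))
  ys <- -m * grid_coords(nrow(b), plane$pitch)[idx[, 1]] / config$pixel_pitch
  xs <- -m * grid_coords(ncol(b), plane$pitch)[idx[, 2]] / config$pixel_pitch
  r <- ys + centre_index(shape[1])
  c <- xs + centre_index(shape[2])
  w <- b[idx]
  out <- matrix(0, shape[1], shape[2])
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  for (dd in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    rr <- r0 + dd[1]; cc <- c0 + dd[2]
    ww <- w * (if (dd[1]) fr else 1 - fr) * (if (dd[2]) fc else 1 - fc)
    ok <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2] & ww > 0
    if (any(ok)) {
      ii <- (cc[ok] - 1) * shape[1] + rr[ok]
      agg <- rowsum(ww[ok], ii)
      tgt <- as.integer(rownames(agg))
      out[tgt] <- out[tgt] + agg[, 1]
    }
  }
  out
}

#' Axial decorrelation curve of the chaotic PSF
#'
#' Cross-correlates the PSF at the reference object distance `config$u` with
#' PSFs simulated at axial offsets `du_values`, returning the normalized
#' correlation peak for each offset. The full width at half maximum of this
#' curve is the axial resolution of the system, comparable to the direct-
#' imaging depth of field `8 lambda (u/D)^2`.
#'
#' @param config An [optical_config].
#' @param mask A [pinhole_array] or pre-rasterized matrix.
#' @param du_values Axial offsets in metres; must include 0.
#' @param params A [filter_params]; the curve is the nonlinear-correlation
#'   reconstruction intensity at the origin, normalized to the
#'   autocorrelation value at `du = 0`.
#' @return A data.frame with columns `du` and `peak` (normalized to 1 at 0).
#' @export
axial_response_curve <- function(config, mask, du_values,
                                 params = filter_params()) {
  if (!any(du_values == 0)) stop("du_values must include 0")
  raster <- mask_raster_for(config, mask)
  ref <- simulate_psf(config, raster)
  ctr <- centre_index(config$sensor_shape)
  origin_value <- function(psf) {
    r <- nonlinear_correlation(ref, psf, params$alpha, params$beta, pad = FALSE)
    r$values[ctr[1], ctr[2]]
  }
  norm <- origin_value(ref)
  peak <- vapply(du_values, function(du) {
    if (du == 0) return(1)
    origin_value(simulate_psf(config, raster, source_depth = config$u + du)) / norm
  }, numeric(1))
  data.frame(du = du_values, peak = pmin(1, pmax(0, peak)))
}

#' Spectral decorrelation curve of the chaotic PSF
#'
#' Companion of [axial_response_curve()] sweeping the wavelength at fixed
#' geometry: the normalized correlation peak between the PSF at the reference
#' wavelength `config$wavelength` and the PSFs at `wavelengths`.
#'
#' @param config An [optical_config].
#' @param mask A [pinhole_array] or pre-rasterized matrix.
#' @param wavelengths Wavelengths in metres to sweep.
#' @param params A [filter_params]; see [axial_response_curve()].
#' @return A data.frame with columns `wavelength` and `peak` (1 at the
#'   reference wavelength).
#' @export
spectral_response_curve <- function(config, mask, wavelengths,
                                    params = filter_params()) {
  raster <- mask_raster_for(config, mask)
  ref <- simulate_psf(config, raster)
  ctr <- centre_index(config$sensor_shape)
  origin_value <- function(psf) {
    r <- nonlinear_correlation(ref, psf, params$alpha, params$beta, pad = FALSE)
    r$values[ctr[1], ctr[2]]
  }
  norm <- origin_value(ref)
  peak <- vapply(wavelengths, function(lam) {
    if (lam == config$wavelength) return(1)
    cfg <- config; cfg$wavelength <- lam
    origin_value(simulate_psf(cfg, raster)) / norm
  }, numeric(1))
  data.frame(wavelength = wavelengths, peak = pmin(1, pmax(0, peak)))
}
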