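#' Depth/wavelength-indexed PSF library
#'
#' The catalogue of chaotic point-spread recordings `I_PSF(z, lambda)` built
#' during the one-time training step: a set of [intensity_pattern]s sharing
#' shape and pitch, indexed on a grid of `q` depths times `p` wavelengths.
#' Entries carry a provenance tag (`"measured"` or `"synthesized"`).
#'
#' @param patterns List of [intensity_pattern]s, each with `meta$z` and
#'   `meta$wavelength` set.
#' @param u,v Optional reference geometry (metres) recorded in the manifest.
#' @param provenance Character scalar or vector of per-entry tags.
#' @return An object of class `psf_library` with fields `entries` (list),
#'   `index` (data.frame `z`, `wavelength`, `provenance`), and sorted unique
#'   `z_values` / `wavelengths` axes.
#' @export
psf_library <- function(patterns, u = NA_real_, v = NA_real_,
                        provenance = "measured") {
  stopifnot(length(patterns) >= 1)
  z <- vapply(patterns, function(p) p$meta$z, numeric(1))
  lam <- vapply(patterns, function(p) p$meta$wavelength, numeric(1))
  if (any(is.na(z)) || any(is.na(lam)))
    stop("every library pattern needs z and wavelength metadata")
  shp <- dim(patterns[[1]]$values)
  for (p in patterns) {
    if (!all(dim(p$values) == shp) || p$pitch != patterns[[1]]$pitch)
      stop("all library entries must share shape and pitch")
  }
  provenance <- rep_len(provenance, length(patterns))
  ord <- order(z, lam)
  structure(list(entries = patterns[ord],
                 index = data.frame(z = z[ord], wavelength = lam[ord],
                                    provenance = provenance[ord]),
                 z_values = sort(unique(z)), wavelengths = sort(unique(lam)),
                 u = u, v = v),
            class = "psf_library")
}

#' @export
print.psf_library <- function(x, ...) {
  cat(sprintf("<psf_library> %d entries: %d depths x %d wavelengths (%s)\n",
              nrow(x$index), length(x$z_values), length(x$wavelengths),
              paste(unique(x$index$provenance), collapse = "+")))
  invisible(x)
}

#' Record a PSF library by simulation
#'
#' Simulates the chaotic PSF for every combination of the requested object
#' distances and wavelengths, emulating the manual training scan of the
#' physical system.
#'
#' @param config An [optical_config] (its `u` is the reference distance).
#' @param mask A [pinhole_array] or pre-rasterized matrix.
#' @param z_values Object distances in metres.
#' @param wavelengths Wavelengths in metres.
#' @return A [psf_library] with provenance `"measured"`.
#' @export
record_library <- function(config, mask, z_values = config$u,
                           wavelengths = config$wavelength) {
  raster <- mask_raster_for(config, mask)
  patterns <- list()
  for (z in z_values) for (lam in wavelengths) {
    cfg <- config; cfg$wavelength <- lam
    patterns[[length(patterns) + 1L]] <- simulate_psf(cfg, raster, source_depth = z)
  }
  psf_library(patterns, u = config$u, v = config$v)
}

#' Look up the library entry nearest a (z, wavelength) key
#'
#' @param library A [psf_library].
#' @param z,wavelength Query coordinates in metres.
#' @param tol Optional `(z, wavelength)` tolerances; default half the axial /
#'   spectral grid step (or exact match for singleton axes).
#' @return The matching [intensity_pattern].
#' @export
library_lookup <- function(library, z, wavelength, tol = NULL) {
  if (is.null(tol)) {
    half_step <- function(ax) if (length(ax) > 1) min(diff(ax)) / 2 else Inf
    tol <- c(half_step(library$z_values), half_step(library$wavelengths))
  }
  dz <- abs(library$index$z - z)
  dl <- abs(library$index$wavelength - wavelength)
  score <- dz / max(tol[1], 1e-300) + dl / max(tol[2], 1e-300)
  i <- which.min(score)
  if (dz[i] > tol[1] + 1e-12 || dl[i] > tol[2] + 1e-15)
    stop(sprintf("no library entry within tolerance of (z = %g mm, lambda = %g nm)",
                 z * 1e3, wavelength * 1e9))
  library$entries[[i]]
}

#' Extract one depth/wavelength channel from a single object frame
#'
#' Reconstructs the slice of the scene at `(z, wavelength)` by correlating the
#' single monochrome object frame against the corresponding library PSF with
#' the full [reconstruct_pipeline()]. Channels at other depths or wavelengths
#' decorrelate and contribute only weak background.
#'
#' @param i_o The object frame ([intensity_pattern] or matrix).
#' @param library A [psf_library].
#' @param z,wavelength Channel key (metres); nearest entry within tolerance.
#' @param params A [filter_params].
#' @return A `recon_image`; its `key` field records the matched entry's
#'   coordinates.
#' @export
extract_channel <- function(i_o, library, z, wavelength,
                            params = filter_params()) {
  psf <- library_lookup(library, z, wavelength)
  r <- reconstruct_pipeline(i_o, psf, params)
  r$key <- c(z = psf$meta$z, wavelength = psf$meta$wavelength)
  r
}

#' Isotropically rescale a pattern about the grid centre
#'
#' Resamples the pattern by magnification `gamma` about the optical axis (the
#' grid centre) with bilinear interpolation, keeping the output shape
#' (regions scaled in from outside the grid are zero). This is the transverse
#' scaling that maps chaotic patterns between neighbouring depths or
#' wavelengths and drives the PSF synthesis from boundary recordings.
#'
#' @param i An [intensity_pattern] or matrix.
#' @param gamma Magnification in `[0.5, 2]`; `gamma > 1` enlarges features.
#' @return Same type as the input (metadata preserved for patterns).
#' @export
scale_pattern <- function(i, gamma) {
  if (gamma < 0.5 || gamma > 2) stop("gamma out of the supported range [0.5, 2]")
  v <- as_values(i)
  if (gamma == 1) return(i)
  nr <- nrow(v); nc <- ncol(v)
  cr <- centre_index(nr); cc <- centre_index(nc)
  src_r <- (seq_len(nr) - cr) / gamma + cr
  src_c <- (seq_len(nc) - cc) / gamma + cc
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  # clamp while tracking validity
  valid_r <- r0 >= 1 & r0 <= nr - 1; valid_c <- c0 >= 1 & c0 <= nc - 1
  r0c <- pmin(pmax(r0, 1L), nr - 1L); c0c <- pmin(pmax(c0, 1L), nc - 1L)
  g <- function(ri, ci) v[cbind(rep(ri, times = nc), rep(ci, each = nr))]
  out <- (1 - fr) %o% (1 - fc) * matrix(g(r0c, c0c), nr) +
         fr %o% (1 - fc)       * matrix(g(r0c + 1L, c0c), nr) +
         (1 - fr) %o% fc       * matrix(g(r0c, c0c + 1L), nr) +
         fr %o% fc             * matrix(g(r0c + 1L, c0c + 1L), nr)
  out[!valid_r, ] <- 0
  out[, !valid_c] <- 0
  if (is.matrix(i)) return(out)
  i$values <- pmax(out, 0)
  i
}

#' Estimate the magnification between two chaotic patterns
#'
#' Finds the scale factor `gamma*` maximizing the normalized cross-correlation
#' peak of `scale_pattern(i_a, gamma)` against `i_b`: a coarse grid over
#' `gamma_range` followed by golden-section refinement to 1e-4. This is the
#' measurement performed between the axial or spectral boundary recordings of
#' a library before synthesis.
#'
#' @param i_a,i_b Patterns of identical shape.
#' @param gamma_range Search interval inside `[0.5, 2]`.
#' @param steps Coarse grid size (>= 3).
#' @return `gamma*`, with attribute `"peak"` (the correlation attained).
#' @export
estimate_gamma <- function(i_a, i_b, gamma_range = c(0.9, 1.1), steps = 21L) {
  stopifnot(length(gamma_range) == 2, gamma_range[1] < gamma_range[2], steps >= 3)
  a <- as_values(i_a); b <- as_values(i_b)
  obj <- function(g) ncc_peak(scale_pattern(a, g), b)$peak
  gs <- seq(gamma_range[1], gamma_range[2], length.out = steps)
  vals <- vapply(gs, obj, numeric(1))
  if (diff(range(vals)) < 1e-10)
    stop("flat correlation landscape: cannot estimate gamma")
  i <- which.max(vals)
  lo <- gs[max(1L, i - 1L)]; hi <- gs[min(steps, i + 1L)]
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  while (hi - lo > 1e-4) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- obj(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- obj(x1)
    }
  }
  g <- (lo + hi) / 2
  out <- g
  attr(out, "peak") <- obj(g)
  out
}

#' Linear interpolation / extrapolation of magnification factors
#'
#' Straight-line fit of `gamma` versus an axial or spectral coordinate through
#' two anchor measurements, evaluated at a query coordinate. With the axial
#' anchors `(du = -5 mm, 1.0)` and `(du = +5 mm, 0.975)` the mid-point
#' `du = 0` interpolates to `gamma = 0.9875`.
#'
#' @param coords Numeric length-2: anchor coordinates (distinct).
#' @param gammas Numeric length-2: measured magnifications at the anchors.
#' @param query Coordinate(s) at which to evaluate the fit.
#' @return Interpolated gamma value(s).
#' @export
interpolate_gamma <- function(coords, gammas, query) {
  stopifnot(length(coords) == 2, length(gammas) == 2)
  if (coords[1] == coords[2]) stop("anchor coordinates must be distinct")
  slope <- (gammas[2] - gammas[1]) / (coords[2] - coords[1])
  gammas[1] + slope * (query - coords[1])
}

corner_key <- function(iz, il) paste0(iz, il)

#' Synthesize a full PSF library from four boundary recordings
#'
#' Given the four PSFs recorded at the corners of the `(z, lambda)` calibration
#' rectangle (the axial and spectral limits - four camera shots in total), the
#' magnification between each corner pair is measured with
#' [estimate_gamma()], interpolated linearly across the rectangle, and every
#' interior grid entry is synthesized by rescaling the nearest corner
#' recording with [scale_pattern()]. Synthesized entries carry provenance
#' `"synthesized"` and a quality score (normalized correlation against the
#' corner they came from); corner keys return the measured input unchanged.
#'
#' @param corners A [psf_library] (or list of 4 [intensity_pattern]s) holding
#'   exactly the 4 corner recordings; a missing corner is an error.
#' @param z_values,wavelengths Target axes (metres) spanning the corner
#'   rectangle.
#' @param gamma_range Search range handed to [estimate_gamma()].
#' @return A [psf_library] over the full target grid. Per-entry quality
#'   scores are in `attr(, "quality")`.
#' @export
synthesize_library <- function(corners, z_values, wavelengths,
                               gamma_range = c(0.85, 1.15)) {
  if (inherits(corners, "psf_library")) corners <- corners$entries
  stopifnot(length(corners) == 4)
  z <- vapply(corners, function(p) p$meta$z, numeric(1))
  lam <- vapply(corners, function(p) p$meta$wavelength, numeric(1))
  zr <- range(z); lr <- range(lam)
  cp <- list()
  for (p in corners) {
    iz <- if (p$meta$z == zr[1]) 0L else if (p$meta$z == zr[2]) 1L else NA
    il <- if (p$meta$wavelength == lr[1]) 0L else if (p$meta$wavelength == lr[2]) 1L else NA
    if (is.na(iz) || is.na(il)) stop("corner recordings must sit at the (z, wavelength) rectangle corners")
    cp[[corner_key(iz, il)]] <- p
  }
  if (length(cp) != 4 || !all(c("00", "01", "10", "11") %in% names(cp)))
    stop("missing corner: need recordings at all 4 (z, wavelength) corners")
  single_z <- zr[1] == zr[2]; single_l <- lr[1] == lr[2]
  # gamma measured low -> high along each edge
  gz <- c(`0` = if (single_z) 1 else estimate_gamma(cp[["00"]], cp[["10"]], gamma_range),
          `1` = if (single_z) 1 else estimate_gamma(cp[["01"]], cp[["11"]], gamma_range))
  gl <- c(`0` = if (single_l) 1 else estimate_gamma(cp[["00"]], cp[["01"]], gamma_range),
          `1` = if (single_l) 1 else estimate_gamma(cp[["10"]], cp[["11"]], gamma_range))
  patterns <- list(); prov <- character(); quality <- numeric()
  for (zq in z_values) for (lq in wavelengths) {
    tz <- if (single_z) 0 else (zq - zr[1]) / diff(zr)
    tl <- if (single_l) 0 else (lq - lr[1]) / diff(lr)
    if (tz < -1e-9 || tz > 1 + 1e-9 || tl < -1e-9 || tl > 1 + 1e-9)
      stop("target axes must lie inside the corner rectangle")
    iz <- round(tz); il <- round(tl)
    corner <- cp[[corner_key(iz, il)]]
    if (abs(tz - iz) < 1e-9 && abs(tl - il) < 1e-9) {
      entry <- corner
      entry$meta$z <- zq; entry$meta$wavelength <- lq
      patterns[[length(patterns) + 1L]] <- entry
      prov <- c(prov, "measured"); quality <- c(quality, 1)
      next
    }
    gz_t <- (1 - tl) * gz[["0"]] + tl * gz[["1"]]   # axial gamma at this wavelength
    gl_t <- (1 - tz) * gl[["0"]] + tz * gl[["1"]]   # spectral gamma at this depth
    sz <- 1 + tz * (gz_t - 1)                        # scale rel. low-z corner
    sl <- 1 + tl * (gl_t - 1)
    if (iz == 1) sz <- sz / gz_t                     # re-reference to the near corner
    if (il == 1) sl <- sl / gl_t
    g_tot <- sz * sl
    entry <- scale_pattern(corner, g_tot)
    entry$meta$z <- zq; entry$meta$wavelength <- lq; entry$meta$du <- NA_real_
    patterns[[length(patterns) + 1L]] <- entry
    prov <- c(prov, "synthesized")
    quality <- c(quality, ncc_peak(entry, corner)$peak)
  }
  lib <- psf_library(patterns, provenance = prov)
  attr(lib, "quality") <- quality
  attr(lib, "boundary_shots") <- 4L
  lib
}

#' Depth-wavelength reciprocity transform
#'
#' The chaotic pattern depends on the products `lambda u` and `lambda v`, so
#' changing the wavelength from `lambda_from` to `lambda_to` while scaling
#' both distances by `lambda_from / lambda_to` leaves the pattern unchanged
#' (`lambda_n u_m = lambda_n v_m = constant`). Returns the adjusted
#' `(u', v')`; e.g. moving from 617 nm at `u = 10 cm` to 530 nm gives
#' `u' = 11.64 cm` (about 12 cm).
#'
#' @param u,v Distances in metres (> 0).
#' @param lambda_from,lambda_to Wavelengths in metres (> 0).
#' @return Numeric `(u', v')` in metres.
#' @export
reciprocity_transform <- function(u, v, lambda_from, lambda_to) {
  if (u <= 0 || v <= 0 || lambda_from <= 0 || lambda_to <= 0)
    stop("all reciprocity arguments must be positive")
  (lambda_from / lambda_to) * c(u = u, v = v)
}

#' Correlation scan over distance and wavelength
#'
#' Simulates the chaotic PSF over a grid of distances and wavelengths and
#' cross-correlates each against the reference PSF of `config`. With
#' `fixed_v = FALSE` the object and image distances are scanned jointly
#' (`u = v = uv`); the high-correlation set then forms a ridge (a comb of
#' maxima) along `lambda u = lambda_ref u_ref`, the signature of
#' depth-wavelength reciprocity. With `fixed_v = TRUE` only `u` is scanned at
#' fixed `v`; reciprocity is then broken and only the autocorrelation point
#' survives.
#'
#' @param config An [optical_config]; its `(u, v, wavelength)` is the
#'   reference.
#' @param mask A [pinhole_array] or pre-rasterized matrix.
#' @param uv_values Distances (metres) scanned.
#' @param wavelengths Wavelengths (metres) scanned.
#' @param fixed_v Keep `v = config$v` while scanning `u`?
#' @return A `reciprocity_map`: matrix `length(uv_values) x
#'   length(wavelengths)` of normalized correlation peaks, with the scan axes
#'   and reference stored as attributes.
#' @export
reciprocity_scan <- function(config, mask, uv_values, wavelengths,
                             fixed_v = FALSE) {
  stopifnot(length(uv_values) >= 1, length(wavelengths) >= 1)
  raster <- mask_raster_for(config, mask)
  ref <- simulate_psf(config, raster)
  map <- matrix(NA_real_, length(uv_values), length(wavelengths))
  for (i in seq_along(uv_values)) for (j in seq_along(wavelengths)) {
    cfg <- config
    cfg$u <- uv_values[i]
    cfg$v <- if (fixed_v) config$v else uv_values[i]
    cfg$wavelength <- wavelengths[j]
    map[i, j] <- ncc_peak(ref, simulate_psf(cfg, raster))$peak
  }
  structure(map, uv_values = uv_values, wavelengths = wavelengths,
            reference = c(u = config$u, v = config$v,
                          wavelength = config$wavelength),
            fixed_v = fixed_v, class = c("reciprocity_map", "matrix"))
}

#' Strict local maxima of a correlation scan
#'
#' Grid points whose value exceeds all 8 neighbours and reaches at least
#' `threshold` times the global maximum.
#'
#' @param map A matrix (e.g. a `reciprocity_map`).
#' @param threshold Fraction of the global maximum.
#' @return data.frame with columns `i`, `j`, `value` (plus `uv` and
#'   `wavelength` when the map carries scan axes).
#' @export
scan_local_maxima <- function(map, threshold = 0.8) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(map))
  nr <- nrow(m); nc <- ncol(m)
  thr <- threshold * max(m)
  out <- data.frame(i = integer(), j = integer(), value = numeric())
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- m[i, j]
    if (v < thr) next
    nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (v >= max(nb) && sum(nb == v) == 1)
      out <- rbind(out, data.frame(i = i, j = j, value = v))
  }
  uv <- attr(map, "uv_values"); lam <- attr(map, "wavelengths")
  if (!is.null(uv)) { out$uv <- uv[out$i]; out$wavelength <- lam[out$j] }
  out
}
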