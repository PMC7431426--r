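#' Nominal RGB weights for a wavelength
#'
#' Assigns display-colour weights to a spectral channel by proximity to the
#' nominal red/green/blue primaries (617, 530 and 488 nm class sources):
#' wavelengths below 505 nm stain blue, 505-575 nm green, above 575 nm red,
#' with a linear crossfade of 30 nm around each boundary. Weights are
#' non-negative and sum to 1.
#'
#' @param wavelength Wavelength in metres.
#' @return Named numeric `(red, green, blue)`.
#' @export
wavelength_rgb <- function(wavelength) {
  nm <- wavelength * 1e9
  ramp <- function(x) pmin(1, pmax(0, x))
  blue <- ramp((505 - nm) / 30 + 0.5)
  red <- ramp((nm - 575) / 30 + 0.5)
  green <- pmax(0, 1 - blue - red)
  w <- c(red = red, green = green, blue = blue)
  w / sum(w)
}

bayer_sites <- function(colour, pattern = "RGGB") {
  stopifnot(pattern == "RGGB")
  switch(colour,
         red = list(c(1L, 1L)),
         green = list(c(1L, 2L), c(2L, 1L)),
         blue = list(c(2L, 2L)),
         stop("unknown colour '", colour, "'"))
}

#' Synthetic Bayer filter mosaic of extracted spectral channels
#'
#' Places up to three colour-assigned reconstructions onto an RGGB site grid
#' of twice the linear size (four times the area): each input pixel value is
#' written at its colour's site(s) of the corresponding 2x2 cell (green owns
#' two sites per cell), and sites of missing colours stay zero. This is the
#' software analogue of a colour camera's Bayer filter, applied after the
#' fact to channels extracted from a monochrome frame.
#'
#' @param channels Named list with elements among `red`, `green`, `blue`
#'   (matrices or `recon_image`s of one common shape). Duplicate colour names
#'   are an error.
#' @param pattern Site layout; only `"RGGB"` is supported.
#' @return A `(2 rows) x (2 cols)` mosaic matrix.
#' @export
bayer_mosaic <- function(channels, pattern = "RGGB") {
  nms <- names(channels)
  if (is.null(nms) || !all(nms %in% c("red", "green", "blue")))
    stop("channels must be a named list with names among red, green, blue")
  if (anyDuplicated(nms)) stop("two images claim the same colour")
  if (!length(channels)) stop("empty channel set")
  vals <- lapply(channels, as_values)
  shp <- dim(vals[[1]])
  for (v in vals) if (!all(dim(v) == shp)) stop("channel shapes differ")
  out <- matrix(0, 2L * shp[1], 2L * shp[2])
  rows <- seq_len(shp[1]) * 2L - 1L
  cols <- seq_len(shp[2]) * 2L - 1L
  for (colour in nms) {
    for (site in bayer_sites(colour, pattern)) {
      out[rows + site[1] - 1L, cols + site[2] - 1L] <- vals[[colour]]
    }
  }
  out
}

shift_pad <- function(x, dr, dc) {
  # shift with edge replication
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

#' Bilinear demosaicing of an RGGB mosaic
#'
#' Reconstructs full-resolution red, green and blue planes from a Bayer
#' mosaic by normalized bilinear interpolation (the standard 3x3 kernels).
#'
#' @param mosaic Matrix produced by [bayer_mosaic()] (even dimensions).
#' @param pattern Only `"RGGB"`.
#' @return Named list of matrices `red`, `green`, `blue`, same shape as the
#'   mosaic.
#' @export
demosaic_bilinear <- function(mosaic, pattern = "RGGB") {
  stopifnot(pattern == "RGGB", nrow(mosaic) %% 2 == 0, ncol(mosaic) %% 2 == 0)
  site_mask <- function(colour) {
    m <- matrix(0, nrow(mosaic), ncol(mosaic))
    rows <- seq_len(nrow(mosaic) / 2) * 2L - 1L
    cols <- seq_len(ncol(mosaic) / 2) * 2L - 1L
    for (site in bayer_sites(colour, pattern))
      m[rows + site[1] - 1L, cols + site[2] - 1L] <- 1
    m
  }
  interp <- function(colour) {
    m <- site_mask(colour)
    num <- mosaic * m; den <- m
    acc_n <- num * 0; acc_d <- den * 0
    k <- rbind(c(1, 2, 1), c(2, 4, 2), c(1, 2, 1)) / 4
    for (dr in -1:1) for (dc in -1:1) {
      w <- k[dr + 2, dc + 2]
      acc_n <- acc_n + w * shift_pad(num, dr, dc)
      acc_d <- acc_d + w * shift_pad(den, dr, dc)
    }
    acc_n / pmax(acc_d, .Machine$double.eps)
  }
  list(red = interp("red"), green = interp("green"), blue = interp("blue"))
}

channel_meta <- function(ch, field, default = NA_real_) {
  x <- ch[[field]]
  if (is.null(x)) default else x
}

#' Compose extracted channels into a multicolour image
#'
#' Stains each spectral channel with the display weights of its wavelength
#' ([wavelength_rgb()]) and sums them into an RGB image, optionally restricted
#' to the channels of one depth.
#'
#' @param channels List of channel entries, each a list with `image` (matrix
#'   or `recon_image`), `wavelength` (metres) and optional `z`, `t`.
#' @param z Optional depth filter (metres, matched within `tol`).
#' @param tol Depth matching tolerance.
#' @param normalize Scale each channel to unit maximum before staining, and
#'   the composite to unit maximum after.
#' @return An `H x W x 3` array (red, green, blue planes).
#' @export
compose_colour <- function(channels, z = NULL, tol = 1e-9, normalize = TRUE) {
  if (!is.null(z))
    channels <- Filter(function(ch) {
      zc <- channel_meta(ch, "z"); !is.na(zc) && abs(zc - z) <= tol
    }, channels)
  if (!length(channels)) stop("no channel at the requested depth")
  v1 <- as_values(channels[[1]]$image)
  out <- array(0, c(dim(v1), 3L))
  for (ch in channels) {
    v <- as_values(ch$image)
    if (normalize && max(v) > 0) v <- v / max(v)
    w <- wavelength_rgb(ch$wavelength)
    for (k in 1:3) out[, , k] <- out[, , k] + w[k] * v
  }
  if (normalize && max(out) > 0) out <- out / max(out)
  out
}

#' Assemble extracted channels into a 5D datacube
#'
#' Collects per-frame channel extractions into a dense `(x, y, z, lambda, t)`
#' array. One monochrome frame per time point suffices (the single-shot
#' property), and time slices are filled independently - there is no temporal
#' coupling.
#'
#' @param channels List of entries, each with `image`, `z`, `wavelength` and
#'   `t` (any consistent units; used as axis labels). Every `(z, lambda, t)`
#'   combination present must have exactly one entry, and all images must
#'   share one shape.
#' @return A 5D array of dimension `(rows, cols, n_z, n_lambda, n_t)` with
#'   axis vectors in attributes `z_values`, `wavelengths`, `t_values`.
#' @export
assemble_5d <- function(channels) {
  stopifnot(length(channels) >= 1)
  z <- vapply(channels, channel_meta, numeric(1), field = "z")
  lam <- vapply(channels, channel_meta, numeric(1), field = "wavelength")
  tt <- vapply(channels, channel_meta, numeric(1), field = "t", default = 0)
  if (any(is.na(z)) || any(is.na(lam)))
    stop("every channel needs z and wavelength metadata")
  za <- sort(unique(z)); la <- sort(unique(lam)); ta <- sort(unique(tt))
  shp <- dim(as_values(channels[[1]]$image))
  cube <- array(NA_real_, c(shp, length(za), length(la), length(ta)))
  for (i in seq_along(channels)) {
    v <- as_values(channels[[i]]$image)
    if (!all(dim(v) == shp)) stop("inconsistent channel shapes across the cube")
    iz <- match(z[i], za); il <- match(lam[i], la); it <- match(tt[i], ta)
    if (!any(is.na(cube[1, 1, iz, il, it])) && !is.na(cube[1, 1, iz, il, it]))
      stop("duplicate channel at one (z, lambda, t) key")
    cube[, , iz, il, it] <- v
  }
  if (anyNA(cube)) stop("inconsistent axes: some (z, lambda, t) combinations are missing")
  structure(cube, z_values = za, wavelengths = la, t_values = ta,
            class = c("datacube_5d", "array"))
}
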