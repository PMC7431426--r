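# On-disk formats: grayscale TIFF/PNG frames with JSON metadata sidecars,
# CSV mask lists, YAML optical configs and the library directory container.
# Interface units are mm / nm / um; everything is metres in memory.

sidecar_path <- function(path) paste0(path, ".json")

# Pre-quantize a [0,1] image for the TIFF/PNG writers, which map samples by
# q = trunc(x * (2^bits - 1)). Encoding the intended level as (q + 0.49) /
# (2^bits - 1) makes the stored integer exact whether the writer truncates or
# rounds; the 32-bit reader divides by 2^32 (not 2^32 - 1), which the caller
# compensates in the recorded scale factor.
quantize_levels <- function(img01, bits) {
  m <- 2^bits - 1
  q <- round(img01 * m)
  pmin((q + 0.49) / m, 1)
}

meta_to_sidecar <- function(meta, scale, seed = NULL) {
  list(wavelength_nm = if (is.na(meta$wavelength)) NULL else meta$wavelength * 1e9,
       u_mm = if (is.na(meta$z)) NULL else meta$z * 1e3,
       du_mm = if (is.na(meta$du)) NULL else meta$du * 1e3,
       role = meta$role, scale = scale, seed = seed)
}

#' Write an intensity frame to TIFF or PNG
#'
#' Frames are rescaled to the full bit depth with the scale factor recorded in
#' a JSON sidecar (`<path>.json`), so physical units survive the round trip.
#' TIFF supports 8, 16 or 32-bit (float) samples; PNG supports 8 and 16.
#'
#' @param i An [intensity_pattern] (or matrix, written with empty metadata).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits Bits per sample.
#' @param pixel_pitch Pitch recorded when `i` is a bare matrix.
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_intensity <- function(i, path, bits = 16L, pixel_pitch = NA_real_,
                            seed = NULL) {
  if (is.matrix(i)) i <- intensity_pattern(i, if (is.na(pixel_pitch)) 1 else pixel_pitch)
  v <- i$values
  mx <- max(v)
  scale <- if (mx > 0) mx else 1
  img <- quantize_levels(v / scale, bits)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L, 32L)) stop("TIFF bits must be 8, 16 or 32")
    if (bits == 32L) scale <- scale * 2^32 / (2^32 - 1)  # reader divides by 2^32
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8L) stop("PNG frames are written at 8 bits; use TIFF for 16/32-bit")
    png::writePNG(img, path)
  } else stop("unsupported frame format '", ext, "' (use .tif/.tiff/.png)")
  jsonlite::write_json(meta_to_sidecar(i$meta, scale * i$meta$scale, seed),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an intensity frame and its metadata sidecar
#'
#' Grayscale TIFF or PNG; colour frames are rejected. If the JSON sidecar is
#' missing the frame loads with a warning and unknown metadata (scale 1).
#'
#' @param path Frame path.
#' @return An [intensity_pattern] in physical units.
#' @export
read_intensity <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported frame format '", ext, "'")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) stop("colour frames are not supported; expected grayscale")
    img <- img[, , 1]
  }
  sc <- sidecar_path(path)
  meta <- list(wavelength_nm = NULL, u_mm = NULL, du_mm = NULL, role = "psf",
               scale = 1, seed = NULL)
  if (file.exists(sc)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sc, simplifyVector = TRUE))
  } else {
    warning("metadata sidecar missing for '", path, "'; metadata unknown")
  }
  intensity_pattern(img * (meta$scale %||% 1), pitch = 1,
                    wavelength = (meta$wavelength_nm %||% NA_real_) * 1e-9,
                    z = (meta$u_mm %||% NA_real_) * 1e-3,
                    du = (meta$du_mm %||% NA_real_) * 1e-3,
                    role = if (identical(meta$role, "object")) "object" else "psf")
}

#' Write / read a pinhole array as CSV + JSON header
#'
#' The CSV holds one `x_mm, y_mm` row per pinhole; the JSON header
#' (`<path>.json`) records `diameter_um` and `extent_mm`.
#'
#' @param mask A [pinhole_array].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [pinhole_array] (reader).
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "pinhole_array"))
  utils::write.csv(data.frame(x_mm = mask$centers[, 1] * 1e3,
                              y_mm = mask$centers[, 2] * 1e3),
                   path, row.names = FALSE)
  jsonlite::write_json(list(diameter_um = mask$diameter * 1e6,
                            extent_mm = mask$extent * 1e3),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pinhole_array(cbind(df$x_mm, df$y_mm) * 1e-3, hdr$diameter_um * 1e-6,
                hdr$extent_mm * 1e-3)
}

#' Write / read an optical configuration as YAML
#'
#' Interface units: millimetres for distances, nanometres for the wavelength,
#' micrometres for the pixel pitch.
#'
#' @param config An [optical_config].
#' @param path YAML path.
#' @return `path` invisibly (writer); an [optical_config] (reader).
#' @export
write_optical_config <- function(config, path) {
  stopifnot(inherits(config, "optical_config"))
  yaml::write_yaml(list(u_mm = config$u * 1e3, v_mm = config$v * 1e3,
                        wavelength_nm = config$wavelength * 1e9,
                        sensor_shape = as.integer(config$sensor_shape),
                        pixel_pitch_um = config$pixel_pitch * 1e6,
                        grid_oversample = config$grid_oversample),
                   path)
  invisible(path)
}

#' @rdname write_optical_config
#' @export
read_optical_config <- function(path) {
  y <- yaml::read_yaml(path)
  optical_config(u = y$u_mm * 1e-3, v = y$v_mm * 1e-3,
                 wavelength = y$wavelength_nm * 1e-9,
                 sensor_shape = y$sensor_shape,
                 pixel_pitch = y$pixel_pitch_um * 1e-6,
                 grid_oversample = y$grid_oversample %||% 1L)
}

#' Write a PSF library to a directory container
#'
#' One 32-bit grayscale TIFF per entry plus a `library.json` manifest holding the
#' geometry, the axes (`du_mm`, `lambda_nm`) and per-entry file/provenance
#' records.
#'
#' @param library A [psf_library].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "psf_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- library$u
  du <- library$index$z - (if (is.na(u)) 0 else u)
  entries <- vector("list", nrow(library$index))
  for (k in seq_len(nrow(library$index))) {
    fn <- sprintf("psf_du%+05.1fmm_%04.0fnm.tif", du[k] * 1e3,
                  library$index$wavelength[k] * 1e9)
    e <- library$entries[[k]]
    v <- e$values
    mx <- max(v); if (mx == 0) mx <- 1
    tiff::writeTIFF(quantize_levels(v / mx, 32L), file.path(dir, fn),
                    bits.per.sample = 32L)
    entries[[k]] <- list(du_mm = du[k] * 1e3,
                         lambda_nm = library$index$wavelength[k] * 1e9,
                         file = fn, provenance = library$index$provenance[k],
                         scale = mx * 2^32 / (2^32 - 1), pitch_um = e$pitch * 1e6)
  }
  jsonlite::write_json(
    list(u_mm = if (is.na(u)) NULL else u * 1e3,
         v_mm = if (is.na(library$v)) NULL else library$v * 1e3,
         axes = list(du_mm = sort(unique(du)) * 1e3,
                     lambda_nm = library$wavelengths * 1e9),
         entries = entries),
    file.path(dir, "library.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "library.json"), simplifyVector = FALSE)
  u <- (man$u_mm %||% NA_real_) * 1e-3
  patterns <- list(); prov <- character()
  for (e in man$entries) {
    img <- tiff::readTIFF(file.path(dir, e$file))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    z <- (if (is.na(u)) 0 else u) + e$du_mm * 1e-3
    patterns[[length(patterns) + 1L]] <-
      intensity_pattern(img * e$scale, pitch = e$pitch_um * 1e-6,
                        wavelength = e$lambda_nm * 1e-9, z = z,
                        du = e$du_mm * 1e-3, role = "psf")
    prov <- c(prov, e$provenance)
  }
  psf_library(patterns, u = u, v = (man$v_mm %||% NA_real_) * 1e-3,
              provenance = prov)
}
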