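# Internal numerics shared across modules: centered grids, FFT helpers,
# padding/cropping and block downsampling. The spatial convention everywhere is
# row ~ y, column ~ x, origin at the grid centre (index floor(n/2)+1, 1-based),
# matching the DC position after fftshift.

grid_coords <- function(n, pitch) (seq_len(n) - (n %/% 2L + 1L)) * pitch

centre_index <- function(n) n %/% 2L + 1L

fft_freqs <- function(n, pitch) {
  # cycles per metre, in FFT (wrap-around) order
  k <- c(seq.int(0L, n - n %/% 2L - 1L), seq.int(-(n %/% 2L), -1L))
  k / (n * pitch)
}

fftshift <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c(seq.int(nr %/% 2L + 1L, nr), seq_len(nr %/% 2L)),
    c(seq.int(nc %/% 2L + 1L, nc), seq_len(nc %/% 2L)), drop = FALSE]
}

ifftshift <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c(seq.int(nr - nr %/% 2L + 1L, nr), seq_len(nr - nr %/% 2L)),
    c(seq.int(nc - nc %/% 2L + 1L, nc), seq_len(nc - nc %/% 2L)), drop = FALSE]
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

pad_centre <- function(x, shape, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(shape[1] >= nr, shape[2] >= nc)
  out <- matrix(if (is.complex(x)) complex(real = fill) else fill, shape[1], shape[2])
  r0 <- centre_index(shape[1]) - centre_index(nr)
  c0 <- centre_index(shape[2]) - centre_index(nc)
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- x
  out
}

crop_centre <- function(x, shape) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(shape[1] <= nr, shape[2] <= nc)
  r0 <- centre_index(nr) - centre_index(shape[1])
  c0 <- centre_index(nc) - centre_index(shape[2])
  x[r0 + seq_len(shape[1]), c0 + seq_len(shape[2]), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Block-average an (r*f) x (c*f) matrix down to r x c.
box_downsample <- function(x, factor) {
  if (factor == 1L) return(x)
  nr <- nrow(x) %/% factor
  nc <- ncol(x) %/% factor
  dim(x) <- c(factor, nr * factor * nc)
  x <- colSums(x)                 # sum over row sub-blocks -> (nr, f, nc)
  dim(x) <- c(nr, factor, nc)
  x <- aperm(x, c(2L, 1L, 3L))
  dim(x) <- c(factor, nr * nc)
  x <- colSums(x)                 # sum over column sub-blocks
  matrix(x / factor^2, nr, nc)
}

#' Normalized cross-correlation peak between two patterns
#'
#' Removes each pattern's mean, cross-correlates them circularly via FFT and
#' returns the largest correlation value normalized by the product of the two
#' pattern energies, together with the shift (rows, cols) at which it occurs.
#' The value is 1 for identical patterns and near 0 for unrelated chaotic
#' patterns; it is the similarity measure used for axial/spectral response
#' curves, reciprocity scans and PSF-synthesis quality scores.
#'
#' @param a,b Matrices or [intensity_pattern] objects of equal shape.
#' @param subpixel Refine the peak location to sub-pixel accuracy by a
#'   parabolic fit through the peak and its neighbours?
#' @return A list with `peak` (normalized correlation maximum, clipped to
#'   `[0, 1]`) and `shift`, the `(rows, cols)` displacement of `b` relative
#'   to `a` at the peak (integer unless `subpixel`).
#' @export
ncc_peak <- function(a, b, subpixel = FALSE) {
  a <- as_values(a); b <- as_values(b)
  stopifnot(all(dim(a) == dim(b)))
  a0 <- a - mean(a); b0 <- b - mean(b)
  den <- sqrt(sum(a0^2) * sum(b0^2))
  if (den == 0) return(list(peak = 0, shift = c(0L, 0L)))
  cc <- Re(stats::fft(stats::fft(b0) * Conj(stats::fft(a0)), inverse = TRUE)) / length(a0)
  i <- arrayInd(which.max(cc), dim(cc))
  shift <- c(i[1] - 1L, i[2] - 1L)
  shift <- ifelse(shift > dim(a) / 2, shift - dim(a), shift)
  if (subpixel) {
    frac <- function(axis) {
      n <- dim(cc)[axis]
      pick <- function(d) {
        idx <- i; idx[axis] <- (idx[axis] - 1L + d) %% n + 1L
        cc[idx[1], idx[2]]
      }
      vm <- pick(-1L); v0 <- pick(0L); vp <- pick(1L)
      d2 <- vm - 2 * v0 + vp
      if (d2 >= 0) 0 else 0.5 * (vm - vp) / d2
    }
    shift <- shift + c(frac(1L), frac(2L))
    return(list(peak = min(1, max(0, max(cc) / den)), shift = shift))
  }
  list(peak = min(1, max(0, max(cc) / den)), shift = as.integer(shift))
}

as_values <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "intensity_pattern") || inherits(x, "recon_image")) return(x$values)
  if (inherits(x, "complex_field")) stop("expected an intensity (real) image, got a complex field")
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"), " as an image")
}
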