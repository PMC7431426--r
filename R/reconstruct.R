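#' Reconstruction filter parameters
#'
#' Parameters of the correlation reconstruction pipeline: the nonlinear filter
#' exponents `alpha` (on the PSF spectral magnitude) and `beta` (on the object
#' spectral magnitude), plus the optional post-processing stages. The
#' published operating point is `alpha = 0, beta = 0.6`; `(1, 1)` reduces to a
#' matched filter and `(0, 1)` to a phase-only filter.
#'
#' @param alpha,beta Spectral-magnitude exponents in `[-1, 1]`.
#' @param lowpass_cutoff Low-pass cutoff as a fraction of Nyquist in `(0, 1]`;
#'   1 disables the stage.
#' @param median_kernel Odd median-filter kernel size in pixels; 1 disables.
#' @param spectrum_filter_strength Spectrum-domain correlation filter strength
#'   in `[0, 1]`; 0 disables.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(alpha = 0, beta = 0.6, lowpass_cutoff = 1,
                          median_kernel = 1L, spectrum_filter_strength = 0) {
  median_kernel <- as.integer(median_kernel)
  stopifnot(alpha >= -1, alpha <= 1, beta >= -1, beta <= 1,
            lowpass_cutoff > 0, lowpass_cutoff <= 1,
            median_kernel >= 1L, median_kernel %% 2L == 1L,
            spectrum_filter_strength >= 0, spectrum_filter_strength <= 1)
  structure(list(alpha = alpha, beta = beta, lowpass_cutoff = lowpass_cutoff,
                 median_kernel = median_kernel,
                 spectrum_filter_strength = spectrum_filter_strength),
            class = "filter_params")
}

new_recon_image <- function(values, params = NULL, key = NULL) {
  structure(list(values = values, params = params, key = key),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d, peak %.3g\n",
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

# Mean-remove and optionally zero-pad both inputs; run f on their FFTs; return
# |IFFT|, fftshifted so zero lag sits at the centre pixel, cropped back to the
# input shape when padded.
correlate_fft <- function(i_o, i_psf, pad, combine) {
  o <- as_values(i_o); p <- as_values(i_psf)
  if (!all(dim(o) == dim(p))) stop("object and PSF frames must have identical shapes")
  o <- o - mean(o); p <- p - mean(p)
  shp <- dim(o)
  if (pad) { o <- pad_centre(o, 2L * shp); p <- pad_centre(p, 2L * shp) }
  g <- combine(stats::fft(o), stats::fft(p))
  cc <- fftshift(Mod(ifft2(g)))
  if (pad) cc <- crop_centre(cc, shp)
  cc
}

#' Conventional correlation reconstruction (matched / phase-only filter)
#'
#' Cross-correlates the object frame with a PSF frame after mean removal:
#' `matched` uses `F_O * conj(F_PSF)`; `phase_only` divides by `|F_PSF|`
#' (zero-magnitude bins pass zero). The reconstruction magnitude `|C|` is
#' returned with zero shift at the image centre.
#'
#' @param i_o Object frame ([intensity_pattern] or matrix).
#' @param i_psf PSF frame of identical shape.
#' @param kind `"matched"` or `"phase_only"`.
#' @param pad Zero-pad to twice the linear size before transforming (linear
#'   rather than circular correlation); `FALSE` gives the exact circular
#'   convention.
#' @return A `recon_image`.
#' @export
cross_correlate <- function(i_o, i_psf, kind = c("matched", "phase_only"),
                            pad = TRUE) {
  kind <- match.arg(kind)
  cc <- correlate_fft(i_o, i_psf, pad, function(fo, fp) {
    if (kind == "matched") fo * Conj(fp)
    else {
      m <- Mod(fp)
      out <- fo * Conj(fp)
      nz <- m > 0
      out[nz] <- out[nz] / m[nz]
      out[!nz] <- 0
      out
    }
  })
  new_recon_image(cc, params = list(kind = kind))
}

#' Nonlinear correlation reconstruction
#'
#' The adaptive correlation filter at the heart of the chaotic-wave
#' reconstruction: both Fourier magnitudes are raised to tunable exponents
#' while their phases are kept,
#' `C = |IFT( |F_PSF|^alpha e^(-i arg F_PSF) |F_O|^beta e^(+i arg F_O) )|`,
#' after removing each frame's mean (emulating correlation of bipolar
#' signals). Zero-magnitude bins always pass zero, so `(alpha, beta) = (1, 1)`
#' is exactly the matched filter and `(0, 1)` exactly the phase-only filter.
#' Intermediate exponents (the published `alpha = 0, beta = 0.6`) suppress the
#' correlation background far below either classical filter.
#'
#' @inheritParams cross_correlate
#' @param alpha Exponent on the PSF spectral magnitude.
#' @param beta Exponent on the object spectral magnitude.
#' @return A `recon_image`.
#' @export
nonlinear_correlation <- function(i_o, i_psf, alpha = 0, beta = 0.6, pad = TRUE) {
  cc <- correlate_fft(i_o, i_psf, pad, function(fo, fp) {
    mo <- Mod(fo); mp <- Mod(fp)
    wo <- ifelse(mo > 0, mo^beta, 0)
    wp <- ifelse(mp > 0, mp^alpha, 0)
    wo * wp * exp(1i * (Arg(fo) - Arg(fp)))
  })
  new_recon_image(cc, params = list(alpha = alpha, beta = beta))
}

#' Shannon entropy of a reconstruction window
#'
#' `S = -sum(phi * log(phi))` over a square window, where `phi` are the window
#' values normalized to unit sum. A clean, delta-like reconstruction has low
#' entropy; a noisy background has entropy approaching `log(N)` for an
#' `N`-pixel window. Minimizing this entropy is the recipe used to select the
#' nonlinear-filter exponents.
#'
#' @param image A `recon_image`, [intensity_pattern] or matrix of
#'   non-negative values.
#' @param window Window side length in pixels; values larger than the image
#'   use the whole image.
#' @param center `(row, col)` of the window centre; default is the global
#'   maximum.
#' @return Entropy in nats, in `[0, log(window pixel count)]`.
#' @export
recon_entropy <- function(image, window = 32L, center = NULL) {
  v <- as_values(image)
  window <- min(as.integer(window), dim(v))
  if (is.null(center)) center <- arrayInd(which.max(v), dim(v))
  h <- window %/% 2L
  r0 <- center[1] - h; c0 <- center[2] - h
  r1 <- r0 + window - 1L; c1 <- c0 + window - 1L
  r0 <- max(1L, min(r0, nrow(v) - window + 1L))
  c0 <- max(1L, min(c0, ncol(v) - window + 1L))
  w <- v[r0:(r0 + window - 1L), c0:(c0 + window - 1L)]
  s <- sum(w)
  if (s == 0) stop("entropy undefined for an all-zero window")
  phi <- w / s
  phi <- phi[phi > 0]
  -sum(phi * log(phi))
}

#' Entropy-minimizing search for nonlinear-filter exponents
#'
#' Evaluates the nonlinear correlation on a grid of `(alpha, beta)` values and
#' returns the pair minimizing the entropy of a window centred on each
#' reconstruction's peak. Ties break deterministically towards the smallest
#' `alpha`, then the smallest `beta`.
#'
#' @inheritParams cross_correlate
#' @param alpha_grid,beta_grid Numeric grids of exponents (non-empty). The
#'   defaults bracket the published operating point.
#' @param window Entropy window size in pixels.
#' @return A [filter_params] carrying the selected exponents, with attribute
#'   `"entropy"` (the winning value).
#' @export
search_filter_params <- function(i_o, i_psf, alpha_grid = 0,
                                 beta_grid = seq(0.2, 1, by = 0.1),
                                 window = 32L) {
  stopifnot(length(alpha_grid) >= 1, length(beta_grid) >= 1)
  best <- NULL; best_s <- Inf
  for (a in sort(alpha_grid)) for (b in sort(beta_grid)) {
    r <- nonlinear_correlation(i_o, i_psf, a, b)
    s <- recon_entropy(r, window)
    if (s < best_s) { best_s <- s; best <- c(a, b) }
  }
  out <- filter_params(alpha = best[1], beta = best[2])
  attr(out, "entropy") <- best_s
  out
}

#' Circular low-pass filter
#'
#' Keeps spatial frequencies inside a circular mask of radius
#' `cutoff x Nyquist` (per-axis normalized radius); `cutoff = 1` passes the
#' full band unchanged.
#'
#' @param image Matrix or [intensity_pattern].
#' @param cutoff Fraction of Nyquist in `(0, 1]`.
#' @return A matrix.
#' @export
lowpass_filter <- function(image, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  v <- as_values(image)
  if (cutoff >= 1) return(v)
  fy <- fft_freqs(nrow(v), 1) * 2  # units of Nyquist
  fx <- fft_freqs(ncol(v), 1) * 2
  keep <- outer(fy^2, fx^2, `+`) <= cutoff^2
  Re(ifft2(stats::fft(v) * keep))
}

#' Median filter with replicated edges
#'
#' Standard rank filter over a `kernel x kernel` window; the image border is
#' replicated before filtering so edge pixels use a full window.
#' `kernel = 1` is the identity.
#'
#' @param image Matrix or [intensity_pattern].
#' @param kernel Odd window side in pixels.
#' @return A matrix.
#' @export
median_filter <- function(image, kernel) {
  kernel <- as.integer(kernel)
  stopifnot(kernel >= 1L, kernel %% 2L == 1L)
  v <- as_values(image)
  if (kernel == 1L) return(v)
  h <- kernel %/% 2L
  pad <- v[c(rep(1L, h), seq_len(nrow(v)), rep(nrow(v), h)),
           c(rep(1L, h), seq_len(ncol(v)), rep(ncol(v), h))]
  lo <- min(pad); hi <- max(pad)
  if (hi == lo) return(v)
  filt <- EBImage::medianFilter((pad - lo) / (hi - lo), size = h)
  out <- filt * (hi - lo) + lo
  out[h + seq_len(nrow(v)), h + seq_len(ncol(v))]
}

#' Spectrum-domain correlation filter
#'
#' Reweights the object spectrum by the local agreement between the object
#' and PSF spectral magnitudes: the band-wise product `|F_O| |F_PSF|` is
#' smoothed over neighbouring frequency bins and normalized by the smoothed
#' band powers (a local normalized correlation of the two magnitude spectra,
#' in `[0, 1]`; identically 1 when the frames coincide), and the object
#' spectrum is multiplied by `w^strength`. Frequency bands present in both
#' frames are kept; bands carried by only one (typically noise) are
#' attenuated. `strength = 0` returns the input unchanged.
#'
#' @param i_o Object frame (matrix or [intensity_pattern]).
#' @param i_psf PSF frame of identical shape.
#' @param strength Exponent in `[0, 1]`.
#' @param smooth_sigma Gaussian smoothing of the agreement map, in frequency
#'   bins.
#' @return The filtered object frame as a matrix (its mean is preserved).
#' @export
spectrum_domain_filter <- function(i_o, i_psf, strength, smooth_sigma = 2) {
  stopifnot(strength >= 0, strength <= 1)
  o <- as_values(i_o)
  if (strength == 0) return(o)
  p <- as_values(i_psf)
  if (!all(dim(o) == dim(p))) stop("object and PSF frames must have identical shapes")
  mo <- mean(o)
  fo <- stats::fft(o - mo)
  fp <- stats::fft(p - mean(p))
  # wrap-around gaussian smoothing across frequency bins
  gy <- stats::dnorm(fft_freqs(nrow(o), 1) * nrow(o), sd = smooth_sigma)
  gx <- stats::dnorm(fft_freqs(ncol(o), 1) * ncol(o), sd = smooth_sigma)
  ker <- stats::fft(outer(gy, gx) / sum(gy) / sum(gx))
  smooth <- function(x) Re(ifft2(stats::fft(x) * ker))
  num <- smooth(Mod(fo) * Mod(fp))
  den <- sqrt(pmax(smooth(Mod(fo)^2), 0) * pmax(smooth(Mod(fp)^2), 0))
  w <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 0)
  Re(ifft2(fo * w^strength)) + mo
}

#' Full correlation reconstruction pipeline
#'
#' Applies, in order: low-pass filtering of the object frame, the
#' spectrum-domain correlation filter, the nonlinear correlation against the
#' PSF, and median filtering of the reconstruction magnitude. Each stage is
#' skipped at its neutral parameter value (see [filter_params()]), so the
#' default runs the bare nonlinear correlation and
#' `filter_params(1, 1)` with all stages off reproduces the matched filter.
#'
#' @inheritParams cross_correlate
#' @param params A [filter_params].
#' @return A `recon_image` whose `params` records the pipeline settings.
#' @export
reconstruct_pipeline <- function(i_o, i_psf, params = filter_params(), pad = TRUE) {
  stopifnot(inherits(params, "filter_params"))
  o <- as_values(i_o)
  if (params$lowpass_cutoff < 1) o <- lowpass_filter(o, params$lowpass_cutoff)
  if (params$spectrum_filter_strength > 0)
    o <- spectrum_domain_filter(o, i_psf, params$spectrum_filter_strength)
  r <- nonlinear_correlation(o, i_psf, params$alpha, params$beta, pad = pad)
  if (params$median_kernel > 1L) r$values <- median_filter(r$values, params$median_kernel)
  r$params <- params
  r
}

#' Peak signal-to-noise ratio of a reconstruction
#'
#' Peak height above the background mean, divided by the background standard
#' deviation, where the background excludes a disc of `exclusion_radius`
#' pixels around the peak. Infinite for an ideal delta-like reconstruction on
#' a constant background.
#'
#' @param image A `recon_image`, [intensity_pattern] or matrix.
#' @param exclusion_radius Radius (pixels) of the excluded disc.
#' @param peak Optional `(row, col)` at which to take the peak; default is
#'   the global maximum.
#' @return Scalar SNR.
#' @export
peak_snr <- function(image, exclusion_radius = 8L, peak = NULL) {
  v <- as_values(image)
  if (is.null(peak)) peak <- arrayInd(which.max(v), dim(v))
  pv <- v[peak[1], peak[2]]
  d2 <- outer((seq_len(nrow(v)) - peak[1])^2, (seq_len(ncol(v)) - peak[2])^2, `+`)
  bg <- v[d2 > exclusion_radius^2]
  if (!length(bg)) stop("exclusion disc covers the whole image")
  s <- stats::sd(bg)
  if (s == 0) return(if (pv > mean(bg)) Inf else 0)
  (pv - mean(bg)) / s
}
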