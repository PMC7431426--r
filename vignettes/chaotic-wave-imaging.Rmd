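---
title: "Chaotic-wave lensless imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic-wave lensless imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(qrap5d)
```

## The imaging model

A quasi-random array of pinholes (QRAP) placed between a scene and a bare
monochrome sensor turns every incoherent point source into a *chaotic wave*: a
quasi-random intensity pattern `I_PSF` that covers the whole sensor and is
unique to the source's depth `z` and wavelength `lambda`. Because the source
points of a scene are mutually incoherent, their patterns add in intensity, so
the single recorded frame is a convolution,

    I_O = sum_{i,j} O(lambda_i, z_j) (x) I_PSF(lambda_i, z_j),

and each depth/wavelength channel can be recovered by cross-correlating `I_O`
with the corresponding library pattern: `O' = I_O * I_PSF = O (x) L`, where
`L` (the autocorrelation of `I_PSF`) is delta-like for a well-designed mask.
Everything in this package serves that one equation: simulating `I_PSF`,
shaping the mask so `L` is sharp, computing the correlation well, and managing
the `(z, lambda)` library.

### Scalar Fresnel simulator

`simulate_psf()` propagates a paraxial spherical wave from the source to the
mask (a quadratic phase factor, `point_source_to_mask()`), multiplies by the
binary mask transmission, and propagates the distance `v` to the sensor with
`fresnel_propagate()`. Two standard propagator forms are provided:

* **transfer-function form** — the Fresnel kernel applied in frequency space.
  It preserves the grid and conserves energy exactly, and is valid for
  distances up to `n * pitch^2 / lambda` (`max_transfer_distance()`). All PSF
  simulation uses this form and refuses geometries outside its regime.
* **impulse-response (single-transform) form** — valid at long range, where
  the output grid rescales to `lambda * d / (n * pitch)`. It is provided for
  free-space propagation outside the imaging regime.

Fields are zero-padded to twice their linear size before each transform to
suppress wrap-around, and intensities are simulated on a grid
`grid_oversample` times finer than the sensor, then box-averaged onto sensor
pixels — the discrete analogue of pixel integration.

**Sampling of the source phase.** The spherical phase oscillates faster
towards the mask edge (local frequency `r / (lambda z)`). For off-axis
sources this tilt can exceed the grid Nyquist limit even when the on-axis
curvature is resolved; an aliased tilt silently wraps the pattern to a wrong
position. `simulate_psf()` therefore checks the maximum local frequency over
the open mask area: within the limit it samples the phase directly (the
lateral shift covariance of the pattern is then an emergent property, which
the tests verify to sub-pixel accuracy); beyond it, the tilt is factored out
analytically — in the paraxial model a source offset translates the pattern
rigidly by `-(v/z) * offset`, exactly — and the on-axis pattern is simulated
on a grid of twice the sensor extent and translated, so content shifts in
from beyond the sensor edge. If even the on-axis curvature is undersampled
the function warns and suggests a larger `grid_oversample`. The full 8 mm
mask at u = 10 cm needs `grid_oversample = 4` on a 512^2, 16 um sensor.

### Forward model for scenes

`simulate_object_intensity()` accepts point emitters (summed one by one —
exact, slow) and planar bitmap objects. Planes take a convolution fast path:
the bitmap is magnified by `v/z`, inverted through the axis, splatted onto an
extended sensor-pitch grid (bilinear, intensity-conserving) and convolved with
the on-axis PSF simulated on that extended grid. The point-sum and
convolution paths agree to well under 2% RMS when the magnified object pixels
land on the sensor lattice; the acceptance suite checks exactly this.

## Mask design

`generate_rap()` draws pinhole centres from two independent uniform streams
(one per coordinate, both derived from one master seed), rejecting candidates
closer than one diameter to an accepted hole — touching holes are forbidden;
the minimum centre separation equals the diameter. The published mask scale
(2000 holes of 80 um in 8 mm x 8 mm, a 15.7% fill) is comfortably feasible
under this rule.

The design objective `snr_objective()` is the peak SNR of the nonlinear
autocorrelation of the on-axis PSF: peak height over the background standard
deviation outside an exclusion disc (8 px default). The exact estimator used
by the original optimization is not published in the main text; this
peak/sigma form is the package's stated stand-in, and it is deterministic for
a fixed mask so the greedy search below is well defined.

* `optimize_layer1()` scores many independent random masks (published budget:
  1000) and keeps the argmax.
* `optimize_layer2()` then sweeps the pinholes in index order, trying
  `±step` moves along x and y, accepting only strict SNR improvements that
  keep the mask valid; ties keep the incumbent, so the accepted-SNR trace is
  strictly increasing and the result never falls below the layer-1 winner.
  One sweep over ~2000 pinholes is ~8000 evaluations, matching the published
  "about 10,000 iterations". SNR evaluations inside the loops should use a
  reduced grid (e.g. a 64^2 sensor); re-score the final mask at full
  resolution.

`mask_diameter()` — the `D` in the resolution formulas below — is the larger
side of the mask extent. For the square fabricated masks this is the quoted
mask size, and it is the aperture that the lateral and axial resolution of
the system actually follow; the diagonal would overstate `D` by root 2 and
both formula checks by 2x.

## Reconstruction

`nonlinear_correlation()` computes

    C = | IFT( |F_PSF|^alpha e^{-i arg F_PSF} . |F_O|^beta e^{+i arg F_O} ) |

after subtracting each frame's mean (the means carry no shift information and
correlation of non-negative signals has a large background; mean removal
emulates bipolar signals without a second exposure). `alpha` weights the PSF
spectrum and `beta` the object spectrum — with this assignment the published
operating point `(alpha = 0, beta = 0.6)` makes the PSF factor phase-only,
which matches how the filter is described alongside the phase-only filter.
Zero-magnitude bins always pass zero, so `(1, 1)` reduces *exactly* to the
matched filter and `(0, 1)` to the phase-only filter; the tests assert both
identities to floating precision. Correlations are FFT-based; by default the
inputs are zero-padded to twice their linear size (linear correlation, no
wrap-around), with `pad = FALSE` giving the exact circular convention under
which shift equivariance is bit-exact.

The full `reconstruct_pipeline()` applies, in order: circular low-pass
filtering of the object frame, the spectrum-domain correlation filter
(`spectrum_domain_filter()` — the object spectrum is reweighted by the
smoothed, normalized agreement `|F_O||F_PSF|`, a stated stand-in for the
supplementary definition), the nonlinear correlation, and a median filter on
the reconstruction magnitude. Every stage is skippable at its neutral
parameter; the defaults run the bare nonlinear correlation.

`search_filter_params()` selects `(alpha, beta)` by minimizing the Shannon
entropy of a window centred on the reconstruction peak — a sharp, delta-like
peak has low entropy, a noisy background a high one. The window defaults to
32 x 32 (not stated by the source system; chosen to cover the peak plus local
background at the default geometries), the default grid is `alpha = 0`,
`beta = 0.2 ... 1.0`, bracketing the published operating point, and ties break
towards the smallest exponents.

## PSF library, reciprocity and synthesis

In the paraxial model the chaotic pattern depends on the wavelength and
distances only through the products `lambda u` and `lambda v`. Scaling
`(u, v)` by `k` and `lambda` by `1/k` therefore leaves the pattern unchanged —
depth-wavelength reciprocity ("colour from depth and depth from colour") —
and the tests verify a normalized correlation of ~1 under exactly this joint
scaling. `reciprocity_scan()` reproduces the two published scan structures: a
joint `(u = v, lambda)` scan shows a comb of correlation maxima along
`lambda u = const`, while scanning `u` alone with `v` fixed leaves only the
autocorrelation point, which is why a calibrated system is not
depth-wavelength ambiguous.

Between neighbouring depths (or wavelengths) the dominant change of the
pattern is an isotropic magnification about the optical axis.
`estimate_gamma()` measures it by maximizing the correlation of
`scale_pattern(I_a, gamma)` against `I_b` (coarse grid, then golden-section
to 1e-4); `scale_pattern()` resamples bilinearly about the grid centre — the
optical axis, which is where the magnification is anchored in this geometry —
with zero fill at the edges. `interpolate_gamma()` carries the measured
values linearly across the library: the axial anchors `(du = -5 mm, 1.0)` and
`(+5 mm, 0.975)` interpolate to 0.9875 at `du = 0`. For the spectral case a
straight line through the published anchors gives 0.987 while the source
system reports 0.986; that value may have been measured directly rather than
interpolated, so both paths exist and neither is asserted against the other.

`synthesize_library()` builds the full `(z, lambda)` grid from the four
corner recordings only — four camera shots: the gamma between each corner
pair is estimated, interpolated bilinearly across the rectangle, and each
interior entry is synthesized by rescaling the nearest corner (smallest
scaling distance, hence least interpolation error). Entries carry a
provenance tag and a quality score (correlation against their source corner).
Synthesized mid-depth PSFs correlate with directly simulated ones at >= 0.7
in the noiseless tests; residual mismatch is real physics — the Fresnel
kernel width changes slightly with depth, which a pure magnification cannot
capture.

## The partial-sensor, wide-field-of-view demonstration

With only the central third of the sensor active, a direct imager loses every
point whose geometric image falls outside the window. The chaotic wave
spreads each point's signature over the whole sensor, so the window still
records a usable (partial) pattern far beyond that limit. Under the exact
paraxial shift invariance the simulator reproduces, correlating a
*windowed* PSF with a *windowed* object frame fails precisely at twice the
direct limit (the shifted window no longer overlaps the reference window), so
the package demonstrates the two regimes separately:

* both frames through the central third, point at 1.5x the direct limit —
  the regime the partial-sensor experiment operates in ("beyond the field of
  view limit of direct imaging");
* the full-sensor library PSF from training against a central-third object
  frame, point at 2x the direct limit — the "partial random intensity
  distribution reconstructs the complete information" property, with full
  correlation overlap.

Both reconstruct the displaced point at its true position with peak SNR far
above 5. "Central third" means the central third of each linear axis (about
1/9 of the pixels).

## Multicolour composition

`bayer_mosaic()` writes up to three colour-assigned channels onto an RGGB
site grid of twice the linear size (4x area; one R, two G, one B site per
2x2 cell), the software analogue of a colour camera's filter mosaic;
`demosaic_bilinear()` inverts it with the standard 3x3 kernels, and both the
mosaic and the directly composed RGB image (`compose_colour()`) are produced
since the display route is a matter of taste. Non-primary wavelengths are
stained by proximity to the 617/530/488 nm class primaries with a 30 nm
linear crossfade (`wavelength_rgb()`). `assemble_5d()` stacks extracted
channels into a dense `(x, y, z, lambda, t)` cube; time slices are filled
independently — one monochrome frame per time point is all the method needs.

## Synthetic data: what it emulates and what it does not

The fixtures module renders three-bar resolution elements at stated line-pair
frequencies (8 lp/mm -> 125 um period), crosshairs, point grids and arbitrary
bitmaps; builds multi-plane, multi-wavelength scenes with the published
layouts (e.g. planes 10 mm and 3 mm apart under 530/617 nm illumination); and
applies seeded Poisson shot noise, Gaussian read noise and 8/16-bit
quantization. It does **not** model: extended (partially coherent) sources —
the recording pinhole of the physical system has finite diameter, which
broadens `L` beyond the simulated limit; full LED spectra — `led_lines()`
samples an LED of stated FWHM into 7 Gaussian-weighted monochromatic
emitters, but the monochromatic default is what all stated conditions use;
sensor dark current,
blooming or fixed-pattern noise; and any non-paraxial propagation. Passing
tests therefore certify the computational pipeline and the paraxial physics,
not camera-grade radiometry.

## Numerical choices and problem sizes

* Default characterization geometry: u = v = 10 cm, 530 nm, 256^2 sensor at
  12 um, 2 mm mask with 100 x 80 um pinholes (12.6% fill, same hole size and
  fill class as the fabricated mask). A PSF simulation at this size is a
  single padded 512^2 transform pair, which keeps response curves and scans
  interactive; the resolution-formula checks run at this size. The full
  8 mm / 2000-pinhole mask is exercised at a
  512^2 sensor (16 um pitch, `grid_oversample = 4`) for the field-of-view
  and autocorrelation checks.
* Reciprocity scans use a 64^2 sensor (36 um pitch, oversample 2) over a
  20 x 20 `(u, lambda)` grid — 800 small PSF simulations — with the mask
  extent chosen so the source curvature stays Nyquist-resolved at the
  shortest scanned distance.
* Correlation measures: response curves and scans that compare patterns at
  *different* library coordinates use the nonlinear-correlation value at the
  origin normalized to the autocorrelation (the discriminating measure a
  channel extraction actually applies); `ncc_peak()` (global normalized
  correlation, max over shifts) is used where pattern *identity* up to a
  shift is the question (reciprocity, synthesis quality, gamma estimation).
* On-disk frames: 8/16-bit TIFF/PNG with a JSON sidecar recording the scale
  back to physical units; the library container uses 32-bit TIFF with a
  compensated scale so that write/read is a projection onto a ~1e-10 grid
  and repeated round trips are bit-exact.
* Degenerate inputs: all-zero entropy windows, empty scenes, non-overlapping
  pinholes, out-of-range gammas and missing library corners all raise errors
  rather than guessing.

## Known limitations

The simulator is scalar and paraxial; at numerical apertures where the
Fresnel approximation degrades (mask much wider than the distances) both the
resolution formulas and reciprocity hold only approximately — matching the
physical claim, which is likewise restricted to the paraxial regime. The
SNR objective and the spectrum-domain filter are stated stand-ins for
supplementary definitions that are not in the main text. Library synthesis
assumes the magnification model; far outside the calibrated boundaries it
degrades gracefully (the quality score drops) but is not re-anchored by new
measurements.
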