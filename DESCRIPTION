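Package: qrap5d
Title: Lensless Single-Shot 5D Imaging with Chaotic Waves from Quasi-Random Pinhole Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for lensless, single-shot,
    multispectral multidimensional imaging through a quasi-random array of
    pinholes (QRAP). Provides a scalar-Fresnel incoherent imaging simulator for
    chaotic-wave point spread functions, two-layer SNR optimization of pinhole
    layouts, nonlinear cross-correlation reconstruction with entropy-driven
    parameter selection, management and synthesis of depth/wavelength PSF
    libraries exploiting depth-wavelength reciprocity, and assembly of
    reconstructed channels into multicolour images and 5D (x, y, z, lambda, t)
    datacubes. Includes a synthetic fixture generator (resolution targets,
    multi-plane multispectral scenes, sensor noise) so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
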