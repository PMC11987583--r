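Package: fourd
Title: Fourier Ring Anisotropy and Depolarisation Correction for Fibre Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies and corrects polarisation bias in fluorescence
    micrographs of labelled fibres (collagen, actin and similar
    fibrillar structures). Computes Fourier ring anisotropy spectra
    (cos2/sin2 orientation moments per spatial frequency) from
    polarisation-resolved image pairs or single images, estimates the
    excitation-polarisation operator from an unaligned calibration
    image, and removes it with a frequency-space inverse multiplier
    (Fourier Ring Depolarisation), whole-frame or patch-wise.
    Includes a synthetic fibre-field simulator with controllable
    intrinsic alignment, polarisation bias, PSF blur and Poisson and
    Gaussian noise, plus patch-wise Fourier angle and eccentricity
    alignment maps and axial circular statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
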