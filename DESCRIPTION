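Package: ssbeam
Title: Sidelobe-Suppressed Bessel Beams for Light-Sheet Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for sidelobe-suppressed Bessel
    beams (SSBB) in light-sheet fluorescence microscopy. Implements the
    two-component Bessel superposition model and its constrained amplitude
    optimization, axicon phase-mask synthesis with random multiplexing for
    spatial light modulators, band-limited angular-spectrum diffraction
    propagation, scanned light-sheet and system axial PSF modelling with
    Richardson-Lucy deconvolution, synthetic scattering bead-phantom image
    stacks, and the image-quality metrics (FWHM and 1/e2 widths, sidelobe
    tables, SNR, CNR, oblique stage-scan unshearing) used to compare SSBB
    against standard Bessel-beam light-sheets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
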