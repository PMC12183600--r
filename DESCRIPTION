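Package: georquant
Title: Quantification of Glycerol Electrooxidation Products from HPLC-DAD
    Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the product panel of the glycerol
    electrooxidation reaction (GEOR) from diode-array-detector HPLC
    chromatograms. Provides a seeded synthetic chromatogram generator,
    morphological baseline estimation, peak detection, trapezoidal
    integration and retention-time assignment against a compound library,
    linear calibration with ICH-style validation statistics (LOD, LOQ,
    repeatability, recovery), a two-wavelength indirect quantification of
    the co-eluting formic acid / glyceraldehyde pair, two-Gaussian
    deconvolution of partially overlapped peaks, and electrochemical
    reporting of product selectivity and Faradaic efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
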