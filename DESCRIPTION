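Package: smallfieldOF
Title: Small-Field Output Factors and Detector Output Correction Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determination of field output factors for small static
    megavoltage photon fields from dual reference detectors (radiochromic
    film dose maps and a two-channel plastic scintillator), and of
    detector-specific output correction factors for solid-state detectors.
    Implements FWHM-based field sizing and equivalent square field size,
    volume-averaging corrections from a bivariate Gaussian fit of the
    central dose distribution with a closed-form erf expression, Cerenkov
    light-ratio calibration and correction for plastic scintillators,
    maximum-likelihood (SD-weighted) fitting of the Sauer-Wilbert field
    output factor function with bootstrap uncertainties, fitting of the
    TRS-483 analytic output correction factor curve, summary-statistics
    Student's t-tests, and a synthetic measurement-campaign generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
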