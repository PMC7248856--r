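Package: camspec
Title: Chemometric Authentication of Camellia Oil from ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of rapeseed-oil adulteration in
    camellia oil from attenuated total reflectance Fourier-transform
    infrared (ATR-FTIR) spectra. Implements the I1119/I1096 ester C-O
    band-ratio purity screen, Savitzky-Golay smoothing and first-derivative
    preprocessing, principal component analysis with loading-based
    wavenumber selection, Fisher linear discriminant analysis with
    leave-one-out cross-validation, and NIPALS partial least squares
    regression with calibration figures-of-merit (slope, offset, R2,
    RMSEC, RMSECV). Ships a calibrated synthetic spectrum generator for
    seven edible oils and camellia/rapeseed blend designs so the whole
    workflow is reproducible without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
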