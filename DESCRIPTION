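Package: drscascade
Title: Cascaded Linear-SVM Classification of Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for intraoperative tissue discrimination from diffuse
    reflectance spectroscopy (DRS): white/dark reference calibration,
    two-band stitching and 800 nm normalization of spectra; a two-stage
    linear support-vector-machine cascade (fat versus rest, then healthy
    colorectal wall versus tumor) with repeated stratified ten-fold
    cross-validation; Matthews-correlation-coefficient based evaluation;
    tumor-depth labeling and depth-sweep analysis; and a
    sensitivity-constrained (zero false negative) decision threshold for
    comparison with surgeon judgement. Includes a physics-motivated
    synthetic spectra generator (Gaussian pseudo-chromophore bands and a
    diffusion-approximation reflectance model) so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
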