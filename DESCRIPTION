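Package: dectrsp
Title: Proton Relative Stopping Power from Dual-Energy CT Material Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives proton relative stopping power (RSP) volumes from
    dual-energy CT effective atomic number (Zeff) and relative electron
    density (RED) maps via the Bethe-Bloch stopping-power ratio, with
    reference-value physics (Mayneord effective atomic number, Bragg
    additivity mean excitation energy, theoretical electron density), a
    voxelized tissue-characterization phantom simulator with calibrated
    Gaussian noise, and the ROI-based accuracy-evaluation statistics used
    in phantom QA (percent error, residuals, tissue-category MAPE, central
    noise sigma, paired Body-versus-Head comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
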