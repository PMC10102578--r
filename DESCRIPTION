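Package: breathsig
Title: Discriminative Metabolic Signatures from Online Breath Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of online secondary electrospray ionization
    high-resolution mass spectrometry (SESI/HRMS) breath recordings: spectral
    resampling, exhalation-window detection, peak picking and trapezoidal
    integration into log2 TIC-normalized breath profiles; surrogate variable
    adjustment and empirical-Bayes moderated t-statistics for differential
    m/z features; leakage-proof repeated stratified cross-validation with
    Boruta feature selection and linear support vector machine classification;
    and mass-based putative annotation with adduct/isotope arithmetic, formula
    enumeration and mummichog-style pathway enrichment. Includes a synthetic
    cohort and raw-recording generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
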