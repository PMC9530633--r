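Package: thrombospectra
Title: Hyperspectral Reflectance Characterisation of Coronary Thrombus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for characterising aspirated coronary thrombus from
    hyperspectral reflectance images (150 bands, 470-900 nm). Pixels are
    classified by two-pass k-means clustering (a full-image pass to separate
    filter, ice, blood and thrombus, then a thrombus-only pass yielding
    compositional k-fractions per sample), unmixed per pixel against basis
    spectra of plasma, red blood cells, filter substrate and water ice, and
    thresholded on thrombus area fraction to audit thrombectomy adequacy.
    Microvascular-injury indices (index of microcirculatory resistance, IMR,
    and microvascular obstruction, MVO) are regressed on the k-fractions with
    linear, power, exponential and saturating-exponential families, with
    permutation p-values. A synthetic-data module generates scenes and cohorts
    with known ground truth so every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    MASS,
    minpack.lm,
    png,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
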