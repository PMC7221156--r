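Package: radrepeat
Title: Test-Retest Repeatability Screening of Prostate mpMRI Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the repeatability of quantitative imaging
    (radiomic) features on paired test-retest prostate multiparametric MRI
    (T2-weighted and apparent diffusion coefficient volumes). Implements a
    307-feature IBSI-aligned extraction engine (first-order statistics,
    intensity histogram, size and shape, grey-level co-occurrence,
    run-length, size-zone and neighbourhood grey-tone difference matrices,
    Laws and undecimated Haar wavelet filter banks), gland-level z-score
    standardisation, automatic low-ADC habitat convergence (15 mm sphere
    and within-lesion sub-median variants), per-feature concordance
    correlation and dynamic-range screening, and recursive R-squared
    redundancy reduction with dynamic-range-maximising representative
    selection. A seeded synthetic phantom cohort generator and a
    designed-concordance feature-matrix simulator make every pipeline stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
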