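Package: peritex
Title: Texture Analysis of the Peritumoral Zone on CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Radiomic texture analysis of the peritumoral zone of solitary
    brain tumors on contrast-enhanced CT, for distinguishing high-grade
    gliomas from solitary brain metastases. Provides image and mask I/O
    (DICOM, PGM, PNG), mu +/- 3 sigma intensity normalization with gray-level
    quantization, seeded region growing with manual-edit support, the
    275-parameter MaZda-style texture feature set (co-occurrence, run-length,
    histogram, absolute gradient, autoregressive model, Haar wavelet
    energies), Fisher and POE+ACC feature reduction, Mann-Whitney screening
    with Bonferroni correction, ROC characterization with Youden-optimal
    cutoffs and DeLong inference, an enter-method linear prediction model
    with collinearity diagnostics, and a synthetic two-class cohort
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
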