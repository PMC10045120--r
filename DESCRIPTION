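Package: redoxcell
Title: Single-Cell Kinetic Modeling of Quinone-Cycling Drug Redox Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental ODE modeling of hydrogen peroxide generation and
    clearance during NQO1-mediated quinone futile cycling of beta-lapachone,
    with per-cell parameterization from single-cell RNA-seq expression
    profiles. Includes equilibrium protein-abundance estimation from mRNA
    levels, finite-difference parameter sensitivity analysis, patient-level
    cohort simulation with Welch's t comparisons of malignant versus
    non-malignant cells, partial least squares regression with VIP scores,
    and a patient-structured synthetic single-cell cohort generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
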