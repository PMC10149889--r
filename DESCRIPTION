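Package: validnet
Title: Psychometric Validity Analysis for Multi-Measure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the psychometric validation of competing measures of a
    construct: convergent-validity correlation matrices with pairwise-complete
    estimation, Fisher-z based averaging and comparison of correlation matrices
    (mean absolute deviation and a chi-squared matrix-equality test),
    double-entry intraclass correlations for profile similarity, self-informant
    agreement with rater-consensus ICCs and paired mean-difference effect sizes,
    correction for attenuation, constrained-correlation likelihood-ratio tests
    for comparing nomological nets, and single-item retest reliability from
    three measurement occasions via the quasi-simplex (Heise) estimator.
    Includes a synthetic-data generator emulating the latent structure such
    studies assume, and bundled correlation tables from a three-study
    validation of loneliness measures as worked examples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
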