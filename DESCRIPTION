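Package: mirhythm
Title: Cosinor Rhythmometry and Strand-Level Analysis of Daily miRNA
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting daily rhythms in mature and precursor
    miRNA expression profiled over a light/dark cycle. Implements
    single-cosinor fits with a fixed 24 h period and the zero-amplitude
    F-test, a genome-wide rhythm screen with expression-quartile
    stratification, acrophase clustering and dark/light ratio statistics,
    a mature/precursor strand-correlation atlas with guide-strand
    assignment, acrophase-clustered target-gene and pathway set selection,
    and tumor-cohort statistics (unpaired t-test, median stratification,
    linear regression, Kaplan-Meier survival with log-rank test). A
    seeded synthetic-data generator reproduces the unbalanced Zeitgeber
    sampling design, strand/precursor family structure and patient-cohort
    structure of a rat colon profiling study, so every pipeline stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
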