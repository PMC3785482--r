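Package: regks
Title: Regulated Kolmogorov-Smirnov Gene-Set Enrichment for Factorial
    Microarray Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for sign-aware ("regulated")
    Kolmogorov-Smirnov gene-set enrichment analysis of factorial microarray
    time-course studies. Covers 75th-percentile normalization of
    present-call intensities, probeset-to-gene collapse, two-way ANOVA
    selection of treatment-response gene sets with false-discovery-rate
    control, a signed KS enrichment statistic combining up- and
    down-regulatee deviations with permutation P-values and left/right
    enrichment scores, leading-edge extraction and membership-matrix
    post-processing, nested derivation of a treatment-modulated response
    subset, and Fisher-exact enrichment of discrete gene lists. A
    synthetic-study generator with planted ground truth makes every stage
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
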