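Package: quieteye
Title: Quiet-Eye Gaze Metrics and Their Linkage to Attention Test Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gaze behaviour recorded with a head-mounted
    eye tracker during a targeting (ball-throwing) task and relating it to
    standardized attention tests in children. Implements dispersion-threshold
    (I-DT) fixation detection with data-quality screening, optical-flash
    synchronization of the gaze and kinematic records, quiet-eye onset and
    duration extraction inside a release-anchored pre-throw window, scoring
    of the d2-R test of attention (concentration performance, error
    percentage) and of a simple reaction-time alertness test (mean RT, SDRT,
    CVRT, correct responses), and a statistical layer with Pearson
    correlations (t and pairs-bootstrap inference), shared-variance F tests,
    canonical correlation analysis and sequential Wilks-lambda permutation
    tests. A synthetic-cohort generator produces raw gaze traces, kinematic
    event annotations and attention-test response records with a planted
    latent cross-domain correlation, supporting end-to-end parameter-recovery
    studies without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
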