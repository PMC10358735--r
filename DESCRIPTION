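Package: acoshort
Title: Ant-Colony-Optimization Short-Form Selection for Ordinal Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving and validating short forms of ordinal
    (Likert-type) questionnaires. Simulates two-wave, two-group item
    responses from a threshold factor model; estimates polychoric
    correlations and fits one-factor, two-factor and bifactor
    confirmatory factor models by diagonally weighted least squares or
    maximum likelihood; computes Cronbach's alpha, McDonald's omega and
    test-retest intraclass correlations; selects fixed-length item
    subsets by ant-colony optimization over multiple psychometric
    criteria (model fit, reliability, retest stability, covariate
    validity) with an exhaustive-search oracle; tests measurement
    invariance across groups with a greedy partial-invariance search;
    and estimates regularized partial-correlation networks with EBIC
    model selection, bootstrap edge intervals and centrality-stability
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    e1071,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
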