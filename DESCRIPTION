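Package: coexhub
Title: Bootstrap Gene Selection, Hub-Gene Significance and Module
    Interaction Networks for Gene Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for weighted gene co-expression network
    analysis on two-class expression experiments. Ranks genes by support
    vector machine recursive feature elimination (SVM-RFE) inside bootstrap
    resamples and tests per-gene informativeness with a signed-rank statistic
    on rank scores; builds weighted co-expression networks from powered
    absolute Pearson correlations with scale-free soft-threshold selection
    and topological-overlap module detection; tests hub-gene significance by
    subsample resampling of weighted connectivity and classifies genes across
    two conditions (differential hub gene analysis); and models directed
    module interaction networks by Bayesian model averaging of lagged linear
    regressions on spline-interpolated module time courses. Includes
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
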