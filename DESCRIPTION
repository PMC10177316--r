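Package: arsefa
Title: Acquiescence Response Style Effects on Exploratory Factor Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and evaluation toolkit for studying how an
    acquiescence response style (ARS) distorts exploratory factor analysis
    of ordinal questionnaire data. Generates item responses from a
    normal-ogive graded response model with one or two content factors and
    a censored-normal ARS factor; estimates Pearson and polychoric
    correlations; fits maximum-likelihood EFA; selects dimensionality by
    BIC, parallel analysis and the CHull procedure on the CAF index;
    resolves rotational freedom by oblimin (gradient projection) and by
    oblique Procrustes rotation toward fully or semi-specified targets
    without factor rescaling; and scores factor recovery (loading RMSE,
    mean maximum absolute bias of zero loadings, factor-correlation RMSE,
    retention rates) against the generating model.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: stats, utils
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
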