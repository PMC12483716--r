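Package: eirmrf
Title: Explanatory Item Response Modeling with Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid modeling of person-by-item binary responses that combines a
    random forest for the fixed part with a logistic mixed model carrying
    crossed random intercepts over persons and items. Provides a Laplace
    fitter for crossed random-intercept logistic models, an iterative
    forest/mixed-model estimation algorithm, an interpretable machine
    learning suite (Gini importance, partial dependence, accumulated local
    effects, Friedman-Popescu H-statistic), accuracy measures (AUC, Brier
    score), synthetic data generators for explanatory item response designs,
    and simulation harnesses comparing the hybrid against pure item response
    models and pure forests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
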