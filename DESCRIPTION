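Package: refgames
Title: Rational Speech Act and Literal Listener Models for One-Shot Reference Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pragmatic reasoning in one-shot referential
    communication games. Implements the basic Rational Speech Act (RSA)
    pragmatic-listener model and a baseline literal-listener model over
    three-object visual contexts, an algorithmic taxonomy of the 24
    experimental conditions spanned by shape/color feature overlap, readers
    and exclusion/aggregation rules for trial-level behavioral data from
    Speaker, Salience and Listener tasks, model-fit and model-comparison
    statistics (Pearson fits with adjusted R-squared, Hittner's modification
    of Dunn and Clark's z for overlapping dependent correlations, exact
    binomial and multinomial tests), a synthetic-agent generator emulating
    crowdsourced participants, and a maximum-likelihood estimator of the
    pragmatic-strategy mixture weight with bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
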