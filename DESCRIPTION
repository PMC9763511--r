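Package: phenolr
Title: Phenotype-Driven Gene Classification with Integrated Likelihood Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-gene Bayesian phenotype models for rare developmental
    disorder cohorts. Integrates sex, quantitative growth measures,
    developmental milestones and Human Phenotype Ontology (HPO) annotations
    through naive Bayes log likelihood ratios; selects informative
    phenotypic terms from an ontology by top-down frequency-bounded
    expansion; combines the per-data-type evidence with five weights
    optimized by simulated annealing on the F1 score; and evaluates models
    by leave-one-out cross-validation, the .632 bootstrap of recall and a
    quartile-based generalization analysis. Ships a synthetic cohort
    generator with planted per-gene effects so the whole pipeline is
    exercisable without access to managed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
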