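Package: opinionpulse
Title: Opinion Mining and Utilization Factor Analysis for Health Topics in Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable analysis chain for studying public
    opinion on a health topic in a social-media post stream alongside
    health-service utilization statistics. Provides seeded synthetic-data
    generators (labeled post corpora, region-year utilization panels,
    visit-age records), text preprocessing with protected-token extraction
    and lexicon POS tagging, pool-based active-learning topic tracking,
    maximum-entropy sentiment classification trained by improved iterative
    scaling, stance detection by polarity propagation on an opinion-aware
    knowledge graph, the yearly Opinion Polarity Ratio statistic, online
    variational LDA topic mining with a dynamic vocabulary, Lasso
    coordinate-descent factor selection with cross-validation, and
    Bayesian-network structure learning with Markov-blanket extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
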