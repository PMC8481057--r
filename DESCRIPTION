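Package: rackstack
Title: Rasch Rating-Scale Stacking and Racking Analysis of Pre/Post Skill Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates observer-scored skill checklists with the Andrich
    rating scale model (joint maximum likelihood with PROX initialisation,
    extreme-score adjustment and model-based standard errors), and measures
    training effects in pre/post designs by stacking (person-ability change)
    and racking (item-difficulty change). Includes psychometric quality
    diagnostics (reliability, separation, Cronbach's alpha, variance
    explained by measures, residual principal contrast, infit/outfit),
    exact and approximate Wilcoxon signed-rank tests, text and ggplot2
    Wright person-item maps, and a synthetic-data generator for pre/post
    ordinal checklist assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
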