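Package: attnrl
Title: Attention-Controlled Reinforcement Learning for Multi-Attribute Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial modelling of multi-attribute, multi-option choice
    behaviour. Implements a reinforcement-learning choice model in which a
    preference vector over the choice set's attribute ranges gates attention
    (selective, winner-take-all versus divided, proportional weighting),
    chosen options are updated by reward prediction error, unchosen options
    decay with a memory-dependent learning rate, and choices follow a softmax
    rule. Provides bespoke choice-sequence statistics (bias and persistence
    indices, run-length distributions, a log-log area test statistic against
    shuffled and sorted reference sequences), maximum-likelihood fitting with
    multi-start bounded optimization and AIC/BIC/pseudo-R2 model comparison,
    and a synthetic task library reproducing a three-condition four-option
    foraging experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
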