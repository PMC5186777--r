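Package: tomnet
Title: Bayesian Network Model of Children's False Belief Reasoning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a five-node causal Bayesian network model of
    children's false belief reasoning on the unexpected-contents task,
    integrating theory-based and simulation-based strategies through a
    mixture conditional probability table. Provides exact inference by
    enumeration, a closed-form false-belief prediction, forward (ancestral)
    simulation of child responses and theory-of-mind scale cohorts, and
    maximum a posteriori estimation of the four model parameters from
    per-task success counts, with a grid-search oracle, broom-style
    tidiers, ggplot2 visualisations, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
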