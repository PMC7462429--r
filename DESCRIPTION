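Package: thoughtnet
Title: Linking Resting-State Connectomes, Ongoing Thought Patterns, and
    Well-Being
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline connecting resting-state
    functional connectomes, experience-sampling reports of ongoing thought,
    and self-reported well-being. Implements Ward clustering and
    varimax-rotated principal component decomposition of thought ratings,
    the network-based statistic (edgewise GLM, suprathreshold component
    extraction, permutation family-wise error control via the maximal
    component size), signed weighted graph metrics including fractional
    strength, test-retest reliability via intraclass correlation, and
    percentile-bootstrap mediation analysis. A synthetic cohort generator
    with planted factor structure, planted connectome components, and a
    known mediation model makes every stage testable without access to
    human data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
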