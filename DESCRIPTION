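Package: regrescue
Title: Condition-Contrast ChIP-Seq Binding-Site Classification and
    Prognostic Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting transcription-factor ChIP-seq binding
    across a two-by-two condition design: replicate peak calls are
    consolidated into consensus sites and classified as lost, rescued or
    enhanced relative to a baseline condition; site sets are compared by a
    base-pair co-occurrence Z-score statistic, profiled around summits, and
    located relative to transcription start sites against a whole-genome
    background. A companion expression arm derives an anchor-gene correlation
    signature (correlated transcripts intersected with a differential
    expression list) and stratifies patients by signature expression using
    Kaplan-Meier, logrank, maximally selected cut-points and Cox proportional
    hazards models. A seeded synthetic-data generator emulates the full study
    design (replicated peak sets with drop-out, coverage tracks, planted
    correlation blocks, cluster-dependent survival) so every stage is
    testable without external data.
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
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
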