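Package: sparseviews
Title: Minimal Diagnostic View Selection for Multi-View Specimen
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-view fine-grained specimen identification with
    differentiable minimal-view selection. Per-view encoding behind a
    pluggable shared-weight encoder contract, gated Transformer fusion
    with learnable view-specific positional encodings, Hard-Concrete L0
    gates with temperature annealing, a compound objective combining
    cross-entropy, supervised contrastive and expected-L0 sparsity
    losses, a sparsity-weight sweep producing a Pareto frontier over
    accuracy versus computational cost, and a margin-based rule that
    selects the recommended minimal diagnostic view subset. Includes a
    synthetic multi-view data generator with a planted informative-view
    subset for end-to-end validation, CSV logging of gate trajectories
    and sweep tables, and top-k prediction reports.
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
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
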