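Package: genevalr
Title: Evaluation Harness for Phenotype-Driven Gene Prioritization with
    Large Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark large language models on phenotype-driven
    gene prioritization for rare-disease diagnosis. Renders zero-shot and
    few-shot prompt templates from HPO term lists or free-text phenotype
    narratives, parses free-text model responses into ranked gene lists with
    HGNC-style symbol canonicalization (approved, previous and alias
    symbols) and gene-name-error screening, and scores three outcomes per
    experiment: task completeness, top-k prediction accuracy (completed and
    overall) and output-structure compliance, with bootstrap confidence
    intervals. Also computes gene-dependent prediction bias statistics
    (observed versus expected prediction odds ratios, publication-count
    correlation, never-predicted genes), cross-iteration and cross-session
    stability tallies, and retrieval-augmented generation indices built
    from HPO gene-phenotype annotations. A synthetic cohort generator and a
    parameterized simulated responder make the full pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
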