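# genevalr

An evaluation harness for benchmarking large language models on
**phenotype-driven gene prioritization** — the rare-disease diagnostic task
of ranking candidate genes from a patient's phenotype profile (HPO terms or
a free-text narrative). It is written for clinical-genomics and ML
researchers who want to measure, with uncertainty and bias diagnostics,
how well an LLM answers "which genes should we test?" — and to validate
that measurement machinery offline before spending money on live APIs.

The harness covers the full methodology:

* **Prompting** — four zero-shot templates (role assignment x
  use-your-trained-knowledge instruction) and a few-shot template with
  worked examples, rendered from HPO term lists or narratives at a top-10
  (challenging) or top-50 (easy) task threshold.
* **Parsing** — free-text responses become ordered canonical gene lists via
  an HGNC-style lexicon (approved, previous and alias symbols;
  case-insensitive; spreadsheet-error symbols like `SEPT1` blocked), with
  fabricated symbol-shaped tokens (e.g. `OPA50`) and refusals flagged.
* **Metrics** — per experiment $e$ and iteration $t$, the rate
  $p_e(t) = \frac{1}{M} \sum_{m=1}^{M} I^{(t)}(m,e)$ for three outcomes:
  task completeness (≥ ⌈K/2⌉ distinct valid genes and no refusal),
  Precision@K accuracy (*completed* and *overall*, the latter scoring
  incomplete tasks as incorrect), and output-structure compliance
  (comma-list dialect or literal "not applicable"). Iteration-averaged
  rates carry 95% percentile-bootstrap CIs (B = 100, resampling cases).
* **Bias** — per-gene observed vs expected prediction counts under a
  pool-frequency null, odds ratios (OR = 0 for never-predicted pool
  genes), and correlation of OR with log10 publication counts.
* **Stability** — discordance tallies across iterations and across
  sessions.
* **RAG** — gene-to-phenotype / phenotype-to-gene document indices from
  HPO annotation tables, deterministic cosine retrieval, prompt
  augmentation.
* **Synthetic world** — a cohort/lexicon/annotation generator and a
  parameterized simulated responder (refusals, truncation, geometric hit
  ranks, citation-skewed fillers, fabrications, format drift) so every
  statistic is checkable by parameter recovery.

## Worked example

Simulate a study world (165-gene pool, 276 cases), run one configuration
of the factorial grid through the simulated backend for three iterations,
and score it:

```r
library(genevalr)

map     <- generate_gene_phenotype_map(n_genes = 165, phenotypes_per_gene = 20, seed = 1)
lex_tsv <- tempfile(fileext = ".tsv")
generate_lexicon(unique(map$gene), path = lex_tsv, seed = 1)
lexicon <- load_lexicon(lex_tsv)
cohort  <- generate_cohort(map, n_cases = 276, seed = 1)

grid      <- build_grid("simulated", "original_role_instruction", "hpo", ks = 50)
backend   <- simulated_backend(lexicon, responder_params(), seed = 1)
responses <- run_grid(grid, cohort, backend, iterations = 3)
scored    <- score_responses(responses, grid, cohort, lexicon, B = 100, seed = 1)
scored$summaries[, c("metric", "mean_rate", "ci_low", "ci_high")]
#> # A tibble: 4 × 4
#>   metric             mean_rate ci_low ci_high
#>   <chr>                  <dbl>  <dbl>   <dbl>
#> 1 completeness           0.867  0.848   0.888
#> 2 accuracy_completed     0.313  0.283   0.348
#> 3 accuracy_overall       0.272  0.246   0.305
#> 4 compliance             0.737  0.708   0.763
```

The default responder refuses 5% of calls, completes 90% of the rest, and
hits the diagnosed gene 30% of the time, so completeness ≈ 0.95 × 0.9 =
0.855, completed accuracy ≈ 0.30 and overall accuracy ≈ 0.86 × 0.30 ≈
0.26 — the estimates above recover those compositions within Monte-Carlo
error, with overall ≤ completed as the two-denominator definitions
require. Bias and stability diagnostics come from the same scored run:

```r
bias <- bias_report(scored$predictions, cohort, k = 50)
never_predicted(bias)$count
#> [1] 0
stability_summary(scored$outcomes)$frac_discordant_completion
#> [1] 0.3514493
```

Every pool gene was predicted at least once (the simulated filler
sampling is unbiased), and ~35% of (case, configuration) experiments
flipped completion across the three iterations — consistent with a
per-call completion probability of about 0.855, since
1 − 0.855³ − 0.145³ ≈ 0.37.

Live backends plug in as any function `(prompt, case, config, iteration)
-> text`; response logs are append-only JSONL, so runs resume and can be
re-scored at any time. A thin command-line front end over the same
functions ships in `inst/cli/genevalr.R` (subcommands `simulate`, `run`,
`score`).

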