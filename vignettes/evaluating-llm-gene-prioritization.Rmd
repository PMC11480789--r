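---
title: "Evaluating LLM-based phenotype-driven gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating LLM-based phenotype-driven gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevalr)
```

## The problem

In rare-disease genomic diagnosis, a clinician has a patient's phenotype
profile — a list of Human Phenotype Ontology (HPO) terms or a free-text
clinical narrative — and wants a ranked list of candidate genes to test.
Large language models can be prompted to produce such lists, but their
free-text answers raise questions that classical gene-prioritization tools
do not: do they complete the task at all, do they return real gene
symbols, do they rank the true diagnostic gene highly, do they obey the
requested output format, and are their answers stable across repeated
calls? `genevalr` is a harness for answering those questions
systematically. It does not call any commercial API itself: responses come
either from a user-supplied backend function or from the package's
parameterized simulated responder, so the whole pipeline is testable
offline and its statistics can be validated by parameter recovery.

## Pipeline overview

An evaluation run is a factorial grid of *experiment configurations*
(model x prompt template x input modality x task threshold $K$), each
applied to every case of a cohort for $T$ repeated iterations
(default $T = 3$). For each response the harness computes three binary
indicators, aggregates them into per-experiment rates with bootstrap
confidence intervals, and then derives bias and stability statistics
across the whole run.

The stages map onto the package surface as:

1. `load_lexicon()` / `canonicalize()` — symbol normalization,
2. `load_cohort()` / `render_prompt()` — inputs and prompts,
3. `run_grid()` — backend execution with permuted order and resumable logs,
4. `parse_response()` / `evaluate_case()` — structured predictions and
   indicators,
5. `summarize_metrics()` — rates and bootstrap CIs,
6. `bias_report()` / `stability_summary()` — run-level diagnostics,
7. `build_index()` / `retrieve()` / `augment_prompt()` — optional
   retrieval-augmented prompting.

## Symbol canonicalization

Model output is free text, so a token like `DDX30`, `p53` or `MMAC1` must
be resolved before scoring. The lexicon (an HGNC-complete-set-style TSV)
maps approved, previous and alias symbols to the approved form; matching
is case-insensitive and the resolution precedence is approved > previous >
alias. Two conservative choices matter:

* **Ambiguous aliases resolve to nothing.** If one alias points at two
  approved genes, crediting either would overstate accuracy. There is no
  authoritative tie-break for this situation, so the harness
  never credits an ambiguous match; the dropped tokens are listed in
  `lexicon$ambiguous_aliases` for inspection.
* **The error-symbol blocklist dominates.** Symbols of the
  spreadsheet-conversion families (`SEPT1`, `MARCH1`, `MAR1`, `DEC1`, ...)
  are blocked before resolution even when the lexicon could resolve them,
  because their appearance in a prediction list is far more likely a
  format artefact than a genuine call. The packaged list is a default,
  not a claim of completeness: pass `error_list_path` to replace it.

Tokens that resolve to nothing but look symbol-shaped (at least three
characters, containing a digit or fully upper-case) are recorded as
*fabricated* — the `OPA50`-style family-extension hallucination mode.
The shape requirement keeps prose words out of the fabrication tally.

## The three outcome metrics

For experiment $e$, iteration $t$ and a cohort of $M$ cases, each metric
is a rate $p_e(t) = \frac{1}{M}\sum_{m=1}^{M} I^{(t)}(m, e)$, averaged
over the $T$ iterations.

* **Task completeness.** A response is complete when it is not a refusal
  and contains at least $\lceil K/2 \rceil$ distinct, valid,
  non-fabricated gene symbols: 25 at $K = 50$. The threshold for
  $K = 10$ is the same rule evaluated at $K = 10$, i.e. 5 — the rule is
  stated for the top-50 task and extrapolated to top-10, a choice
  documented here because no boundary is stated for the harder task.
* **Prediction accuracy (Precision@K).** The indicator is a hit when the
  canonicalized diagnosed gene appears among the first $K$ parsed genes
  (rank order in text is the only available ranking; over-generated
  symbols beyond $K$ do not count). *Completed accuracy* conditions the
  denominator on completed tasks; *overall accuracy* uses all cases and
  scores incomplete tasks as incorrect. Overall accuracy therefore never
  exceeds completed accuracy, a property the test suite checks on random
  logs. When no task completed, completed accuracy is reported as missing
  rather than zero.
* **Structure compliance.** The prompts request a comma-separated list of
  gene symbols, or the literal "not applicable". A response complies when
  it contains a contiguous comma-separated run of at least $K$
  symbol-shaped tokens (whitespace and markdown markup tolerated around
  the commas), or when it is a refusal. The exact regular expression any
  given study used is rarely printed; this operationalization accepts
  over-generation (a run longer than $K$) and tolerates prose *around*
  the run, but not interleaved with it, and the refusal-phrase list is
  configurable. Compliance is judged independently of completeness.

## Uncertainty: the bootstrap

Confidence intervals come from a percentile bootstrap with $B = 100$
replicates (configurable) that resamples *cases* with replacement; all
$T$ iterations of a resampled case move together because repeated calls
on one case are correlated. Each replicate recomputes the
iteration-averaged rate and the 2.5/97.5 percentiles form the interval.
Percentile intervals were chosen over BCa for simplicity and because $B$
is small; the suite verifies calibration empirically (coverage of a known
Bernoulli rate at $M = 200$ over 500 replicates stays within a few points
of nominal — percentile intervals on proportions run slightly below 95%,
which is expected behaviour, not a defect). Everything is deterministic
given a seed.

## Gene-dependent bias

LLMs over-predict famous genes. The harness quantifies this with
observed-versus-expected odds ratios: `prediction_counts()` counts, per
gene, the experiments whose top-$K$ list contains it (once per
experiment, duplicates notwithstanding), and `expected_counts()` supplies
the null expectation
$\mathrm{expected}_g = N \cdot K \cdot \mathrm{poolocc}_g / \sum_h \mathrm{poolocc}_h$ —
a null predictor that fills each of the $K$ slots of each of the $N$
experiments by drawing from the diagnosed-gene pool at pool frequency.
"Expected prediction times" admits several reasonable definitions, so the
null model is a strategy parameter (`uniform_pool` is shipped as an
alternative); the pool-frequency null is the default because it is the
natural "no gene-specific bias beyond case-mix" baseline. The odds ratio
is observed/expected, with $\mathrm{OR} = 0$ exactly when a pool gene was
never predicted — `never_predicted()` lists those genes. Publication bias
is assessed by `citation_correlation()`: Pearson correlation between
$\log_{10}$ publication count and OR (Spearman optional), plus mean ORs
over four equal-width bins of the log count; the binning is equal-width
because only a grouped trend display is being mirrored. Citation counts
are a user-supplied table — the package does not scrape anything.

## Stability

With $T$ iterations per (configuration, case) pair, an experiment is
*discordant* on a metric when its $T$ indicators are not all equal.
`stability_summary()` tallies discordance per metric and, in
cross-session mode, pairs two logs of the same grid and counts
experiments whose number of completed (accurate, compliant) iterations
changed between sessions. The closed form for per-call Bernoulli($p$)
completion, $1 - p^T - (1-p)^T$, anchors the test suite's check at
$p = 0.5$, $T = 3$ (expected discordance 0.75).

## Retrieval-augmented prompting

`build_index()` renders one document per gene (G2P: "The phenotypes
associated with gene *g* include *p1, p2, ...*.") or per phenotype (P2G:
the genes annotated to it) from an HPO annotation table, embeds each
document, and `retrieve()` ranks documents by cosine similarity with a
deterministic lexicographic tie-break. `augment_prompt()` prefixes the
top documents as a `Context:` block — prefixing rather than replacing the
phenotype list, since the retrieved documents are background knowledge,
not a substitute for the patient description. The embedder is a pluggable
contract (string in, fixed-dimension vector out, identified by an
`embedder_id`); the shipped default is a deterministic hashed
bag-of-words embedder (dimension 1024, with a multiplicative scramble and
xor-fold of a rolling token hash so near-identical tokens such as
consecutive numbered labels do not share buckets). A deterministic
embedder makes retrieval exactly reproducible, which proprietary
embedding services cannot offer; adapters for such services plug into the
same contract.

## The synthetic study world

The generator emulates the structure of the real evaluation setting so
that every statistic above can be validated by parameter recovery:

* **Gene pool and cohort.** Defaults: 165 genes, 276 cases, one diagnosed
  gene per case; when cases outnumber the pool every gene appears at
  least once and the remainder follow a $1/\sqrt{\mathrm{rank}}$ skew (a
  few recurrent genes, a long tail of near-singletons). Per-case HPO term
  counts are rounded normal draws, default mean 12 and s.d. 6, clipped to
  at least 1 — inside the 9–35 per-source range seen in curated
  rare-disease cohorts. A `noise_rate` share of terms (default 0.1) comes
  from other genes' annotations. Narratives are template-rendered from
  the same terms, so the two input modalities share ground truth.
* **The simulated responder** (`responder_params()`) encodes refusals
  (`p_refuse`), truncated lists (`1 - p_complete`), a geometric hit rank
  (`p_hit`, `hit_rank_q`), citation-skewed filler sampling
  (weights$^\gamma$, without replacement), family-style fabrications
  (`p_fabricate`, roots with numeric suffixes guaranteed absent from the
  lexicon), duplicates (`p_duplicate`) and format drift (`p_comply`;
  non-compliant responses are numbered lists). Defaults (0.05 refusals,
  0.9 completion, 0.3 hit rate, 0.8 compliance, 5% fabrication) describe
  a mid-quality model; tests that need known truth set parameters
  explicitly.

Under this model the metric truths compose simply: completeness
$= (1-p_\mathrm{refuse}) \cdot p_\mathrm{complete}$, completed accuracy
$= p_\mathrm{hit}$, overall accuracy
$= (1-p_\mathrm{refuse}) \cdot p_\mathrm{complete} \cdot p_\mathrm{hit}$,
and compliance
$= p_\mathrm{refuse} + (1-p_\mathrm{refuse}) \cdot p_\mathrm{complete} \cdot p_\mathrm{comply}$
(a truncated-but-clean list cannot satisfy the $K$-symbol comma-run
pattern, so compliance couples to completeness by construction). The
acceptance suite recovers these compositions at $N = 1000$ cases
$\times\ 3$ iterations.

What the generator does **not** emulate: clinical realism of narratives,
any specific model's linguistic style, semantic relationships between
phenotype labels, or HPO ontology structure (no ancestor closure or
information content). Passing tests therefore demonstrate that the
*measurement machinery* is correct, not that any particular live model
performs at any particular level — live-model performance numbers depend
on closed systems queried at specific dates and are out of scope by
design.

## Numerical and design choices

* Bias-recovery validation uses a *uniform* pool (one case per gene) and
  $K = 50$ over $N = 2000$ simulated experiments: with a uniform pool the
  unbiased responder's filler frequency equals the pool frequency
  exactly, and the larger $K$ keeps per-gene binomial noise small enough
  that every pool gene's OR is individually informative. Skewed pools are
  exercised through the citation-weighted branch instead.
* Problem sizes in the test suite (1000-case recovery runs, 500 bootstrap
  coverage replicates, 2000-experiment bias runs) were chosen so
  Monte-Carlo error sits comfortably inside the asserted tolerances while
  the whole suite stays fast.
* Degenerate inputs: empty experiments error; zero completed tasks yield
  missing completed accuracy; constant OR or citation vectors yield a
  flagged undefined correlation; fewer than three usable genes set a
  `low_n` flag; retrieval with a zero query vector returns zero
  similarities.
* `run_grid()` logs are append-only JSONL keyed by (experiment, case,
  iteration), so reruns resume and re-scoring is a pure function of the
  log — the simulated backend derives a per-call seed from that key,
  making responses independent of execution order.

## Limitations

* Only symbol-form tokens are recognized; a response describing a gene
  without naming it ("the tumor suppressor on 17p") scores as a miss.
  Symbol-form matching is the scoring rule, not an approximation of one.
* The compliance pattern is one operationalization of "comma-separated
  list"; stricter or looser dialects should be tested by configuring the
  pattern set rather than by editing the scorer.
* The packaged error-symbol list covers the well-known date-conversion
  families only.
* Expected-count nulls are simple closed forms; a null that conditions on
  per-case phenotype content would require a model of phenotype-gene
  relatedness, which is deliberately out of scope.
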