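#' Count how many experiments predicted each gene
#'
#' An "experiment" here is one prediction list (one case x configuration x
#' iteration). A gene is counted once per experiment when it appears within
#' the first `k` parsed genes, regardless of how often the response
#' repeated it (parsing already deduplicates).
#'
#' @param predictions List of `parsed_prediction` objects.
#' @param k Ranking cutoff applied to each prediction list.
#' @return Tibble with columns `gene`, `observed`, sorted by decreasing
#'   count.
#' @export
prediction_counts <- function(predictions, k) {
  tops <- lapply(predictions, function(p) utils::head(p$genes, k))
  tab <- table(unlist(tops, use.names = FALSE))
  out <- tibble::tibble(
    gene = names(tab),
    observed = as.integer(tab)
  )
  dplyr::arrange(out, dplyr::desc(.data$observed), .data$gene)
}

#' Expected prediction counts under a null prediction model
#'
#' The default null model imagines a predictor that fills each of the `k`
#' slots of each experiment by drawing from the diagnosed-gene pool in
#' proportion to each gene's pool frequency, so
#' `expected_g = n_experiments * k * pool_occurrences_g / sum(pool occurrences)`.
#' Alternative null models: `"uniform_pool"` spreads the same total evenly
#' over pool genes.
#'
#' @param cohort Cohort tibble (its `diagnosed_gene` column defines the
#'   pool and the pool occurrences).
#' @param n_experiments Number of prediction lists the observed counts were
#'   taken over.
#' @param k Ranking cutoff.
#' @param null_model `"pool_frequency"` (default) or `"uniform_pool"`.
#' @return Tibble with columns `gene`, `pool_occurrences`, `expected`.
#' @export
expected_counts <- function(cohort, n_experiments, k,
                            null_model = c("pool_frequency", "uniform_pool")) {
  null_model <- match.arg(null_model)
  occ <- table(cohort$diagnosed_gene)
  if (length(occ) == 0) {
    stop("Diagnosed-gene pool is empty", call. = FALSE)
  }
  pool <- tibble::tibble(
    gene = names(occ),
    pool_occurrences = as.integer(occ)
  )
  pool$expected <- switch(null_model,
    pool_frequency = n_experiments * k * pool$pool_occurrences /
      sum(pool$pool_occurrences),
    uniform_pool = rep(n_experiments * k / nrow(pool), nrow(pool))
  )
  pool
}

#' Observed-versus-expected prediction odds ratios
#'
#' For each gene, the odds ratio is the observed prediction count divided
#' by its expected count under the null model. Pool genes a model never
#' emitted get `OR = 0`; genes with `expected = 0` (absent from the pool)
#' get a missing odds ratio.
#'
#' @param observed Tibble from [prediction_counts()] (`gene`, `observed`).
#' @param expected Tibble from [expected_counts()] (`gene`,
#'   `pool_occurrences`, `expected`).
#' @return Tibble of bias rows: `gene`, `observed`, `expected`,
#'   `odds_ratio`, `in_diagnosed_pool`, `pool_occurrences`. Contains every
#'   gene present in either input.
#' @export
odds_ratios <- function(observed, expected) {
  rows <- dplyr::full_join(observed, expected, by = "gene")
  rows$observed[is.na(rows$observed)] <- 0L
  rows$in_diagnosed_pool <- !is.na(rows$pool_occurrences)
  rows$pool_occurrences[is.na(rows$pool_occurrences)] <- 0L
  rows$expected[is.na(rows$expected)] <- 0
  rows$odds_ratio <- ifelse(
    rows$expected > 0, rows$observed / rows$expected, NA_real_
  )
  dplyr::arrange(
    rows[, c(
      "gene", "observed", "expected", "odds_ratio",
      "in_diagnosed_pool", "pool_occurrences"
    )],
    dplyr::desc(.data$odds_ratio)
  )
}

#' Correlate prediction odds ratios with publication counts
#'
#' Tests whether a model over-predicts well-studied genes: Pearson (or
#' Spearman) correlation between `log10(citation count)` and the odds
#' ratio, plus mean odds ratios over four equal-width bins of the log
#' count (the grouped view used to display the trend).
#'
#' @param rows Bias-row tibble from [odds_ratios()].
#' @param citations Named numeric vector or two-column table
#'   (`gene`, `count`) of publication counts; genes with missing or
#'   non-positive counts are dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `correlation`, `n`, `low_n` (fewer than 3 usable
#'   genes), `method`, and `groups` (tibble: bin range, mean odds ratio,
#'   gene count).
#' @export
citation_correlation <- function(rows, citations, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(citations)) {
    citations <- stats::setNames(
      as.numeric(citations[[2]]),
      as.character(citations[[1]])
    )
  }
  counts <- citations[rows$gene]
  usable <- !is.na(counts) & counts > 0 & !is.na(rows$odds_ratio)
  logc <- log10(counts[usable])
  or <- rows$odds_ratio[usable]
  n <- sum(usable)
  if (n < 2 || stats::sd(or) == 0 || stats::sd(logc) == 0) {
    warning("Citation-odds correlation undefined (constant or too few values)",
      call. = FALSE
    )
    return(list(
      correlation = NA_real_, n = n, low_n = TRUE, method = method,
      groups = tibble::tibble(
        bin_low = numeric(0), bin_high = numeric(0),
        mean_odds_ratio = numeric(0), n_genes = integer(0)
      )
    ))
  }
  r <- stats::cor(logc, or, method = method)
  breaks <- seq(min(logc), max(logc), length.out = 5)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(logc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  groups <- tibble::tibble(
    bin_low = breaks[seq_len(4)],
    bin_high = breaks[2:5],
    mean_odds_ratio = vapply(
      1:4, function(b) {
        if (any(bin == b)) mean(or[bin == b]) else NA_real_
      },
      numeric(1)
    ),
    n_genes = vapply(1:4, function(b) sum(bin == b), integer(1))
  )
  list(
    correlation = r, n = n, low_n = n < 3, method = method, groups = groups
  )
}

#' Pool genes a model never predicted
#'
#' @param rows Bias-row tibble from [odds_ratios()].
#' @return List with `genes` (pool genes with zero observed predictions,
#'   i.e. `OR = 0`) and `count`.
#' @export
never_predicted <- function(rows) {
  genes <- sort(rows$gene[rows$in_diagnosed_pool & rows$observed == 0])
  list(genes = genes, count = length(genes))
}
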