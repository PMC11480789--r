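METRIC_NAMES <- c(
  "completeness", "accuracy_completed", "accuracy_overall", "compliance"
)

#' Score one parsed response against its case
#'
#' Computes the three binary outcome indicators for one case, experiment
#' and iteration:
#'
#' * `complete` — the response is not a refusal and contains at least
#'   `ceiling(k/2)` distinct valid (non-fabricated, deduplicated) gene
#'   symbols; for the top-50 task the boundary is exactly 25 valid genes,
#'   and for top-10 it is 5.
#' * `accurate` — the diagnosed gene (canonicalized, so previous/alias
#'   forms in the response match) appears among the first `k` parsed genes.
#' * `compliant` — the response format passes
#'   [check_structure_compliance()].
#'
#' @param pred A `parsed_prediction` from [parse_response()].
#' @param case One-row cohort tibble.
#' @param lexicon The `gene_lexicon` the prediction was parsed with.
#' @param k Task threshold (10 or 50).
#' @return One-row tibble: `case_id`, `complete`, `accurate`, `compliant`,
#'   `n_valid_unique`.
#' @export
evaluate_case <- function(pred, case, lexicon, k) {
  stopifnot(inherits(pred, "parsed_prediction"))
  diagnosed <- canonicalize(case$diagnosed_gene[[1]], lexicon)
  if (is.na(diagnosed)) {
    stop(
      "Diagnosed gene `", case$diagnosed_gene[[1]],
      "` does not resolve under the lexicon",
      call. = FALSE
    )
  }
  complete <- !pred$refusal && pred$n_valid_unique >= ceiling(k / 2)
  accurate <- diagnosed %in% utils::head(pred$genes, k)
  compliant <- check_structure_compliance(pred$raw_text, k)
  tibble::tibble(
    case_id = case$case_id[[1]],
    complete = as.integer(complete),
    accurate = as.integer(accurate),
    compliant = as.integer(compliant),
    n_valid_unique = pred$n_valid_unique
  )
}

metric_indicator <- function(records, metric) {
  switch(metric,
    completeness = records$complete,
    compliance = records$compliant,
    # incomplete tasks count as incorrect predictions
    accuracy_overall = records$accurate * records$complete,
    accuracy_completed = records$accurate,
    stop("Unknown metric: ", metric, call. = FALSE)
  )
}

#' Per-iteration outcome rate
#'
#' The rate for one experiment and iteration is the mean indicator over
#' cases. For `accuracy_completed` the denominator is restricted to
#' completed tasks; for `accuracy_overall` all cases count and incomplete
#' tasks are scored incorrect.
#'
#' @param records Outcome-record tibble for a single experiment and
#'   iteration (columns `complete`, `accurate`, `compliant`).
#' @param metric One of `"completeness"`, `"accuracy_completed"`,
#'   `"accuracy_overall"`, `"compliance"`.
#' @return The rate in `[0, 1]`, or `NA` when `accuracy_completed` has no
#'   completed task to condition on.
#' @export
rate_per_iteration <- function(records, metric = METRIC_NAMES) {
  metric <- match.arg(metric)
  if (metric == "accuracy_completed") {
    done <- records$complete == 1
    if (!any(done)) {
      return(NA_real_)
    }
    return(mean(records$accurate[done]))
  }
  mean(metric_indicator(records, metric))
}

# records -> M x T indicator matrices keyed by (case, iteration)
record_matrices <- function(records) {
  cases <- unique(records$case_id)
  iters <- sort(unique(records$iteration))
  shape <- function(col) {
    m <- matrix(NA_real_,
      nrow = length(cases), ncol = length(iters),
      dimnames = list(cases, as.character(iters))
    )
    m[cbind(
      match(records$case_id, cases),
      match(records$iteration, iters)
    )] <- records[[col]]
    m
  }
  list(
    complete = shape("complete"),
    accurate = shape("accurate"),
    compliant = shape("compliant"),
    cases = cases, iterations = iters
  )
}

iteration_rates_from_matrices <- function(mats, metric, idx) {
  switch(metric,
    completeness = colMeans(mats$complete[idx, , drop = FALSE], na.rm = TRUE),
    compliance = colMeans(mats$compliant[idx, , drop = FALSE], na.rm = TRUE),
    accuracy_overall = colMeans(
      (mats$accurate * mats$complete)[idx, , drop = FALSE],
      na.rm = TRUE
    ),
    accuracy_completed = {
      acc <- (mats$accurate * mats$complete)[idx, , drop = FALSE]
      den <- colSums(mats$complete[idx, , drop = FALSE], na.rm = TRUE)
      num <- colSums(acc, na.rm = TRUE)
      ifelse(den > 0, num / den, NA_real_)
    }
  )
}

#' Summarize one experiment's outcome metric with a bootstrap CI
#'
#' The experiment rate is the mean over iterations of the per-iteration
#' rate. Uncertainty comes from a percentile bootstrap that resamples
#' cases with replacement — all iterations of a resampled case move
#' together, because repeated calls on the same case are correlated — and
#' recomputes the iteration-averaged rate on each of `B` replicates.
#'
#' @param records Outcome-record tibble covering the iterations of one
#'   experiment (columns `experiment_id`, `case_id`, `iteration`,
#'   `complete`, `accurate`, `compliant`).
#' @param metric Metric name, see [rate_per_iteration()].
#' @param B Number of bootstrap replicates (default 100).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed; the same seed reproduces the same bounds.
#' @return One-row tibble: `experiment_id`, `metric`, `per_iteration`
#'   (list-column of per-iteration rates), `mean_rate`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_bootstrap`.
#' @export
summarize_experiment <- function(records, metric = METRIC_NAMES, B = 100,
                                 conf = 0.95, seed = NULL) {
  metric <- match.arg(metric)
  if (nrow(records) == 0) {
    stop("Cannot summarize an empty experiment", call. = FALSE)
  }
  experiment_id <- if ("experiment_id" %in% names(records)) {
    unique(records$experiment_id)
  } else {
    NA_character_
  }
  if (length(experiment_id) != 1) {
    stop("summarize_experiment() expects records from a single experiment",
      call. = FALSE
    )
  }
  mats <- record_matrices(records)
  M <- length(mats$cases)
  all_idx <- seq_len(M)
  per_iter <- iteration_rates_from_matrices(mats, metric, all_idx)
  mean_rate <- mean(per_iter, na.rm = TRUE)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(M, M, replace = TRUE)
      mean(iteration_rates_from_matrices(mats, metric, idx), na.rm = TRUE)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble::tibble(
    experiment_id = experiment_id,
    metric = metric,
    per_iteration = list(unname(per_iter)),
    mean_rate = mean_rate,
    ci_low = qs[1],
    ci_high = qs[2],
    n_cases = M,
    n_bootstrap = B
  )
}

#' Summarize all experiments and metrics in an outcome-record table
#'
#' Applies [summarize_experiment()] to every experiment for each requested
#' metric, deriving a per-experiment seed from `seed` so results do not
#' depend on iteration order.
#'
#' @param records Outcome-record tibble (several experiments allowed).
#' @param metrics Metrics to compute (default all four).
#' @param B,conf As in [summarize_experiment()].
#' @param seed Base seed for the bootstrap.
#' @return Tibble with one row per experiment x metric.
#' @export
summarize_metrics <- function(records, metrics = METRIC_NAMES, B = 100,
                              conf = 0.95, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  groups <- split(records, records$experiment_id)
  purrr::map_dfr(names(groups), function(eid) {
    purrr::map_dfr(metrics, function(m) {
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, eid, m)
      summarize_experiment(groups[[eid]], m, B = B, conf = conf, seed = sub_seed)
    })
  })
}
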