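#' Build a factorial experiment grid
#'
#' Full Cartesian product of models x prompt templates x input types x task
#' thresholds, in stable canonical order. The standard GPT-style grid
#' (2 models x 4 zero-shot templates x 2 input types x 2 thresholds) has 32
#' configurations; the Llama2-style grid (3 models x 1 template x 2 x 2)
#' has 12.
#'
#' @param models Character vector of model/backend identifiers.
#' @param templates Character vector of template names.
#' @param input_types Subset of `c("hpo", "free_text")`.
#' @param ks Integer vector of task thresholds.
#' @return Tibble of configurations: `experiment_id`, `model_id`,
#'   `template`, `input_type`, `k`.
#' @export
build_grid <- function(models,
                       templates = c(
                         "original", "original_role",
                         "original_instruction", "original_role_instruction"
                       ),
                       input_types = c("hpo", "free_text"),
                       ks = c(10L, 50L)) {
  for (f in list(models, templates, input_types, ks)) {
    if (length(f) == 0) {
      stop("Every grid factor needs at least one level", call. = FALSE)
    }
  }
  stopifnot(all(input_types %in% c("hpo", "free_text")))
  grid <- tidyr::expand_grid(
    model_id = models, template = templates,
    input_type = input_types, k = as.integer(ks)
  )
  grid$experiment_id <- paste(grid$model_id, grid$template, grid$input_type,
    grid$k,
    sep = "|"
  )
  grid[, c("experiment_id", "model_id", "template", "input_type", "k")]
}

#' Permute the execution order of (configuration, case) pairs
#'
#' Closed-model behaviour can drift over calendar time; permuting the
#' execution sequence decouples configuration from time of execution. The
#' permutation is uniform and reproducible from the seed; each
#' (configuration, case) pair appears exactly once, and its iteration
#' triplet stays contiguous at run time.
#'
#' @param grid Configuration tibble from [build_grid()].
#' @param case_ids Character vector of cohort case ids.
#' @param seed Seed.
#' @return Tibble of `experiment_id`, `case_id` pairs in execution order.
#' @export
permute_order <- function(grid, case_ids, seed = 1) {
  pairs <- tidyr::expand_grid(
    experiment_id = grid$experiment_id, case_id = case_ids
  )
  with_seed(seed, pairs[sample.int(nrow(pairs)), , drop = FALSE])
}

backend_id <- function(backend) attr(backend, "backend_id") %||% "custom"

#' Run an experiment grid against a backend
#'
#' For every (configuration, case) pair — in permuted order — and every
#' iteration, renders the prompt and calls the backend, appending one JSON
#' Lines record per call: `experiment_id`, `case_id`, `iteration`,
#' `prompt`, `response`, `backend`, `timestamp` (plus `error` when the
#' backend failed after all retries; failures are recorded, never fatal).
#' The log is append-only: rerunning over an existing log skips
#' already-recorded (experiment, case, iteration) triples, so interrupted
#' runs resume where they stopped.
#'
#' @param grid Configuration tibble from [build_grid()].
#' @param cohort Cohort tibble.
#' @param backend Backend function `(prompt, case, config, iteration) ->
#'   text`, e.g. [simulated_backend()].
#' @param iterations Repeated calls per pair (default 3).
#' @param out_path Optional JSONL log path (created/appended).
#' @param order_seed Seed for [permute_order()].
#' @param retries Backend retry attempts before recording a failure.
#' @return Tibble of all response records (existing plus new).
#' @export
run_grid <- function(grid, cohort, backend, iterations = 3, out_path = NULL,
                     order_seed = 1, retries = 3) {
  order <- permute_order(grid, cohort$case_id, seed = order_seed)
  existing <- if (!is.null(out_path) && file.exists(out_path)) {
    read_responses(out_path)
  } else {
    tibble::tibble(
      experiment_id = character(0), case_id = character(0),
      iteration = integer(0), prompt = character(0), response = character(0),
      backend = character(0), timestamp = character(0), error = character(0)
    )
  }
  seen <- paste(existing$experiment_id, existing$case_id, existing$iteration,
    sep = "\x1f"
  )
  con <- NULL
  if (!is.null(out_path)) {
    con <- file(out_path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
  }
  new_records <- list()
  for (i in seq_len(nrow(order))) {
    config <- grid[grid$experiment_id == order$experiment_id[i], , drop = FALSE]
    case <- cohort[cohort$case_id == order$case_id[i], , drop = FALSE]
    prompt <- render_prompt(config$template, case, config$input_type, config$k)
    for (t in seq_len(iterations)) {
      key <- paste(config$experiment_id, case$case_id, t, sep = "\x1f")
      if (key %in% seen) next
      response <- NA_character_
      err <- NA_character_
      for (attempt in seq_len(max(1, retries))) {
        result <- tryCatch(
          list(ok = TRUE, value = backend(prompt, case, config, t)),
          error = function(e) list(ok = FALSE, value = conditionMessage(e))
        )
        if (result$ok) {
          response <- result$value
          err <- NA_character_
          break
        }
        err <- result$value
      }
      rec <- tibble::tibble(
        experiment_id = config$experiment_id,
        case_id = case$case_id,
        iteration = t,
        prompt = prompt,
        response = response,
        backend = backend_id(backend),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        error = err
      )
      new_records[[length(new_records) + 1]] <- rec
      if (!is.null(con)) {
        writeLines(
          jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, na = "null"),
          con
        )
      }
    }
  }
  dplyr::bind_rows(existing, dplyr::bind_rows(new_records))
}

#' Read a response log written by [run_grid()]
#'
#' @param path JSONL log path.
#' @return Tibble of response records.
#' @export
read_responses <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) {
      stop("Malformed JSON on response-log line ", i, call. = FALSE)
    })
    tibble::tibble(
      experiment_id = obj$experiment_id, case_id = obj$case_id,
      iteration = as.integer(obj$iteration),
      prompt = obj$prompt %||% NA_character_,
      response = obj$response %||% NA_character_,
      backend = obj$backend %||% NA_character_,
      timestamp = obj$timestamp %||% NA_character_,
      error = obj$error %||% NA_character_
    )
  })
  dplyr::bind_rows(recs)
}

#' Score a response log end to end
#'
#' Parses every response against the lexicon, evaluates the three outcome
#' indicators per record, and returns the outcome table together with
#' parsed predictions (for bias analysis) and per-experiment metric
#' summaries with bootstrap confidence intervals. Records referencing an
#' unknown case or configuration are an error listing the orphans.
#'
#' @param responses Response tibble from [run_grid()]/[read_responses()].
#' @param grid Configuration tibble the log was produced from.
#' @param cohort Cohort tibble.
#' @param lexicon Active `gene_lexicon`.
#' @param B Bootstrap replicates for the summaries.
#' @param seed Bootstrap seed.
#' @return List with `outcomes` (record-level indicators), `predictions`
#'   (tibble with a `parsed` list-column and the config's `k`), and
#'   `summaries` (per experiment x metric).
#' @export
score_responses <- function(responses, grid, cohort, lexicon, B = 100,
                            seed = NULL) {
  orphan_exp <- setdiff(unique(responses$experiment_id), grid$experiment_id)
  orphan_case <- setdiff(unique(responses$case_id), cohort$case_id)
  if (length(orphan_exp) || length(orphan_case)) {
    stop(
      "Orphan response records; unknown experiments: [",
      paste(orphan_exp, collapse = ", "), "]; unknown cases: [",
      paste(orphan_case, collapse = ", "), "]",
      call. = FALSE
    )
  }
  k_of <- stats::setNames(grid$k, grid$experiment_id)
  case_rows <- match(responses$case_id, cohort$case_id)
  parsed <- vector("list", nrow(responses))
  outcomes <- vector("list", nrow(responses))
  for (i in seq_len(nrow(responses))) {
    text <- responses$response[i]
    if (is.na(text)) text <- ""
    k <- k_of[[responses$experiment_id[i]]]
    pred <- parse_response(text, lexicon)
    parsed[[i]] <- pred
    row <- evaluate_case(pred, cohort[case_rows[i], , drop = FALSE], lexicon, k)
    row$experiment_id <- responses$experiment_id[i]
    row$iteration <- responses$iteration[i]
    outcomes[[i]] <- row
  }
  outcomes <- dplyr::bind_rows(outcomes)[, c(
    "experiment_id", "case_id", "iteration",
    "complete", "accurate", "compliant", "n_valid_unique"
  )]
  predictions <- tibble::tibble(
    experiment_id = responses$experiment_id,
    case_id = responses$case_id,
    iteration = responses$iteration,
    k = unname(k_of[responses$experiment_id]),
    parsed = parsed
  )
  list(
    outcomes = outcomes,
    predictions = predictions,
    summaries = summarize_metrics(outcomes, B = B, seed = seed)
  )
}

#' Gene-dependent bias report for a scored run
#'
#' Pools the parsed predictions (optionally restricted to one model or
#' threshold), counts per-gene observed predictions at cutoff `k`,
#' computes expected counts under the null model from the cohort's
#' diagnosed-gene pool, and returns the odds-ratio table.
#'
#' @param predictions Predictions tibble from [score_responses()].
#' @param cohort Cohort tibble.
#' @param k Ranking cutoff.
#' @param null_model Passed to [expected_counts()].
#' @return Bias-row tibble from [odds_ratios()].
#' @export
bias_report <- function(predictions, cohort, k,
                        null_model = c("pool_frequency", "uniform_pool")) {
  observed <- prediction_counts(predictions$parsed, k)
  expected <- expected_counts(cohort, nrow(predictions), k,
    null_model = match.arg(null_model)
  )
  odds_ratios(observed, expected)
}

#' Write the per-experiment metrics report CSV
#'
#' @param summaries Summary tibble from [score_responses()].
#' @param grid Configuration tibble (joined in for the factor columns).
#' @param outcomes Outcome tibble (for per-experiment completed counts).
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
write_metrics_report <- function(summaries, grid, outcomes, path) {
  completed <- dplyr::summarize(
    dplyr::group_by(outcomes, .data$experiment_id),
    n_completed = sum(.data$complete)
  )
  report <- dplyr::left_join(summaries, grid, by = "experiment_id")
  report <- dplyr::left_join(report, completed, by = "experiment_id")
  report <- report[, c(
    "experiment_id", "model_id", "template", "input_type", "k", "metric",
    "mean_rate", "ci_low", "ci_high", "n_cases", "n_completed"
  )]
  readr::write_csv(report, path, progress = FALSE)
  invisible(report)
}
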