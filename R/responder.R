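#' Parameters for the simulated responder
#'
#' The simulated responder stands in for a commercial LLM backend and
#' encodes, as explicit probabilities, the behaviours observed in model
#' responses: outright refusals, truncated gene lists, rank-dependent
#' placement of the true gene, citation-skewed filler choice,
#' family-extension hallucinations, duplicated symbols, and drift away
#' from the requested comma-list format.
#'
#' @param p_complete Probability a non-refusal response carries a full
#'   `k`-slot list (else a truncated list with fewer than `k/2` valid
#'   symbols is emitted).
#' @param p_refuse Probability of a "not applicable" refusal.
#' @param p_hit Probability the diagnosed gene appears in the (full) list.
#' @param hit_rank_q Geometric parameter for the diagnosed gene's rank
#'   given a hit; the rank is `min(rgeom + 1, k)` so hits always land
#'   within the requested list.
#' @param citation_weights Named positive weights over the filler-gene
#'   universe; `NULL` means uniform over the lexicon's approved symbols.
#' @param gamma Exponent skewing filler sampling `prop. weight^gamma`;
#'   `gamma = 0` is unbiased, larger values over-predict heavily cited
#'   genes.
#' @param p_fabricate Per-slot probability of replacing a filler with a
#'   fabricated family-style symbol (an existing root plus an incremented
#'   numeric suffix, guaranteed absent from the lexicon).
#' @param p_comply Probability of clean comma-list formatting (else a
#'   numbered list).
#' @param p_duplicate Per-slot probability of re-emitting an earlier
#'   symbol.
#' @return A `responder_params` list.
#' @export
responder_params <- function(p_complete = 0.9, p_refuse = 0.05, p_hit = 0.3,
                             hit_rank_q = 0.3, citation_weights = NULL,
                             gamma = 0, p_fabricate = 0.05, p_comply = 0.8,
                             p_duplicate = 0.02) {
  probs <- c(
    p_complete = p_complete, p_refuse = p_refuse, p_hit = p_hit,
    hit_rank_q = hit_rank_q, p_fabricate = p_fabricate, p_comply = p_comply,
    p_duplicate = p_duplicate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("All responder probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (!is.null(citation_weights) &&
    (is.null(names(citation_weights)) || any(citation_weights <= 0))) {
    stop("citation_weights must be a named vector of positive weights",
      call. = FALSE
    )
  }
  structure(
    list(
      p_complete = p_complete, p_refuse = p_refuse, p_hit = p_hit,
      hit_rank_q = hit_rank_q, citation_weights = citation_weights,
      gamma = gamma, p_fabricate = p_fabricate, p_comply = p_comply,
      p_duplicate = p_duplicate
    ),
    class = "responder_params"
  )
}

fabricate_symbol <- function(base, lexicon) {
  root <- substr(base, 1, 6)
  for (attempt in seq_len(50)) {
    cand <- paste0(root, sample(30:99, 1))
    if (is.na(canonicalize(cand, lexicon))) {
      return(cand)
    }
  }
  stop("Could not fabricate an unresolvable symbol from root `", root, "`",
    call. = FALSE
  )
}

format_gene_list <- function(symbols, clean) {
  if (clean) {
    paste(symbols, collapse = ", ")
  } else {
    paste0(seq_along(symbols), ". ", symbols, collapse = "\n")
  }
}

#' Simulate one model response for a case
#'
#' Draws from the behaviour model of [responder_params()] using the
#' current RNG state (seed the RNG, or use [simulated_backend()] for
#' per-call derived seeds). With probability `p_refuse` the response is
#' "not applicable"; otherwise with probability `1 - p_complete` a
#' truncated list of fewer than `ceiling(k/2)` valid symbols is emitted.
#' A full response fills `k` slots: the diagnosed gene is inserted at a
#' geometric rank with probability `p_hit`, the remaining slots are filled
#' by weight^gamma-proportional sampling without replacement from the
#' filler universe, each filler slot may be fabricated, and earlier
#' symbols may be duplicated. Formatting is a clean comma list with
#' probability `p_comply`, else a numbered list.
#'
#' @param case One-row cohort tibble.
#' @param params A `responder_params`.
#' @param k Requested list length.
#' @param lexicon The active `gene_lexicon`.
#' @return Response text.
#' @export
simulate_response <- function(case, params, k, lexicon) {
  stopifnot(inherits(params, "responder_params"))
  universe <- if (!is.null(params$citation_weights)) {
    names(params$citation_weights)
  } else {
    lexicon$approved
  }
  weights <- if (!is.null(params$citation_weights)) {
    unname(params$citation_weights)^params$gamma
  } else {
    rep(1, length(universe))
  }
  diagnosed <- canonicalize(case$diagnosed_gene[[1]], lexicon)
  fillers_avail <- setdiff(universe, diagnosed)

  if (stats::runif(1) < params$p_refuse) {
    return("not applicable")
  }
  clean <- stats::runif(1) < params$p_comply

  if (stats::runif(1) >= params$p_complete) {
    # truncated response: strictly fewer than ceiling(k/2) valid symbols
    m <- sample.int(max(1L, ceiling(k / 2) - 1L), 1)
    idx <- sample.int(length(fillers_avail), min(m, length(fillers_avail)),
      prob = weights[match(fillers_avail, universe)]
    )
    return(format_gene_list(fillers_avail[idx], clean))
  }

  hit <- stats::runif(1) < params$p_hit
  n_fill <- k - as.integer(hit)
  if (n_fill > length(fillers_avail) && params$p_fabricate == 0) {
    stop(
      "Need ", n_fill, " filler genes but only ", length(fillers_avail),
      " are available and fabrication is disabled",
      call. = FALSE
    )
  }
  n_draw <- min(n_fill, length(fillers_avail))
  idx <- sample.int(length(fillers_avail), n_draw,
    prob = weights[match(fillers_avail, universe)]
  )
  slots <- fillers_avail[idx]
  # fabricate per filler slot; also tops the list up when fillers ran out
  fab <- stats::runif(length(slots)) < params$p_fabricate
  slots[fab] <- vapply(slots[fab], fabricate_symbol, character(1),
    lexicon = lexicon
  )
  while (length(slots) < n_fill) {
    slots <- c(slots, fabricate_symbol(sample(universe, 1), lexicon))
  }
  if (hit) {
    rank <- min(stats::rgeom(1, params$hit_rank_q) + 1L, k)
    slots <- append(slots, diagnosed, after = rank - 1L)
  }
  if (params$p_duplicate > 0 && length(slots) > 1) {
    dup_after <- which(stats::runif(length(slots)) < params$p_duplicate)
    dup_after <- dup_after[dup_after > 1]
    for (pos in rev(dup_after)) {
      slots <- append(slots, slots[sample.int(pos - 1L, 1)], after = pos)
    }
  }
  format_gene_list(slots, clean)
}

#' A deterministic simulated LLM backend
#'
#' Wraps [simulate_response()] in the backend contract used by
#' [run_grid()]: a function of `(prompt, case, config, iteration)`
#' returning response text. Each call derives its own seed from the base
#' seed and the (experiment, case, iteration) identity, so responses are
#' reproducible and independent of execution order — reruns and resumed
#' runs produce byte-identical response fields. The prompt argument is
#' accepted for contract compatibility; the simulator conditions on the
#' case itself. The declared temperature is 0, matching the deterministic
#' decoding contract used when querying live models.
#'
#' @param lexicon Active `gene_lexicon`.
#' @param params A `responder_params`.
#' @param seed Base seed.
#' @return A backend function with `backend_id` and `declared_params`
#'   attributes.
#' @export
simulated_backend <- function(lexicon, params = responder_params(), seed = 1) {
  force(lexicon)
  force(params)
  force(seed)
  f <- function(prompt, case, config, iteration) {
    call_seed <- derive_seed(seed, config$experiment_id, case$case_id, iteration)
    with_seed(call_seed, {
      simulate_response(case, params, config$k, lexicon)
    })
  }
  attr(f, "backend_id") <- "simulated"
  attr(f, "declared_params") <- list(temperature = 0, model = "simulated")
  f
}
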