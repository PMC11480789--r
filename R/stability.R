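#' Cross-iteration (and cross-session) stability tallies
#'
#' An experiment (one case x configuration) run for T iterations is
#' discordant on a metric when its T indicators are not all equal —
#' temperature-zero decoding does not guarantee identical behaviour across
#' repeated calls, and these tallies quantify how often outcomes actually
#' flip. In cross-session mode a second record set from a later rerun is
#' paired by experiment id and case, and the number of completed (accurate,
#' compliant) iterations per experiment is compared between sessions.
#'
#' @param records Outcome-record tibble with columns `experiment_id`,
#'   `case_id`, `iteration`, `complete`, `accurate`, `compliant`; every
#'   (experiment, case) group needs at least 2 iterations.
#' @param session2 Optional second record tibble with the same experiment
#'   and case ids (a rerun of the same grid in a later session).
#' @return List with `n_experiments`, `n_discordant_completion`,
#'   `n_discordant_accuracy`, `n_discordant_compliance`, per-metric
#'   discordant fractions, and (when `session2` is given) `cross_session`:
#'   a tibble tallying experiments whose per-metric iteration counts
#'   stayed the same versus changed.
#' @export
stability_summary <- function(records, session2 = NULL) {
  key <- function(r) paste(r$experiment_id, r$case_id, sep = "\x1f")
  groups <- split(records, key(records))
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes < 2)) {
    stop("Stability needs at least 2 iterations per experiment; ",
      sum(sizes < 2), " group(s) have fewer",
      call. = FALSE
    )
  }
  discord <- function(col) {
    vapply(groups, function(g) length(unique(g[[col]])) > 1, logical(1))
  }
  d_complete <- discord("complete")
  d_accurate <- discord("accurate")
  d_compliant <- discord("compliant")
  out <- list(
    n_experiments = length(groups),
    n_discordant_completion = sum(d_complete),
    n_discordant_accuracy = sum(d_accurate),
    n_discordant_compliance = sum(d_compliant),
    frac_discordant_completion = mean(d_complete),
    frac_discordant_accuracy = mean(d_accurate),
    frac_discordant_compliance = mean(d_compliant)
  )
  if (!is.null(session2)) {
    g2 <- split(session2, key(session2))
    missing1 <- setdiff(names(g2), names(groups))
    missing2 <- setdiff(names(groups), names(g2))
    if (length(missing1) || length(missing2)) {
      stop(
        "Cross-session experiment sets differ; missing from session 1: [",
        paste(gsub("\x1f", "/", missing1), collapse = ", "),
        "]; missing from session 2: [",
        paste(gsub("\x1f", "/", missing2), collapse = ", "), "]",
        call. = FALSE
      )
    }
    n_iter <- function(gs, col) {
      vapply(gs, function(g) sum(g[[col]]), numeric(1))
    }
    ids <- names(groups)
    out$cross_session <- tibble::tibble(
      metric = c("completion", "accuracy", "compliance"),
      n_same = c(
        sum(n_iter(groups, "complete")[ids] == n_iter(g2, "complete")[ids]),
        sum(n_iter(groups, "accurate")[ids] == n_iter(g2, "accurate")[ids]),
        sum(n_iter(groups, "compliant")[ids] == n_iter(g2, "compliant")[ids])
      )
    )
    out$cross_session$n_changed <- length(groups) - out$cross_session$n_same
  }
  out
}
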