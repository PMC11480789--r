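#' Load an evaluation cohort from JSON Lines
#'
#' Each line is one case: a JSON object with fields `case_id`, `source`,
#' `hpo_terms` (array of `{"id": "HP:NNNNNNN", "label": ...}` objects, may
#' be empty), `free_text` (string, may be empty) and `diagnosed_gene`. A
#' case must carry at least one non-empty phenotype modality (HPO terms or
#' narrative). When a lexicon is supplied, each diagnosed gene must
#' canonicalize under it.
#'
#' @param path Path to the cohort JSONL file.
#' @param lexicon Optional `gene_lexicon`; when given, diagnosed genes are
#'   validated and replaced by their canonical form.
#' @return A tibble with one row per case: columns `case_id`, `source`,
#'   `hpo_terms` (list-column of tibbles with `id`, `label`), `free_text`,
#'   `diagnosed_gene`.
#' @export
load_cohort <- function(path, lexicon = NULL) {
  if (!file.exists(path)) {
    stop("Cannot read cohort file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  cases <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
      error = function(e) {
        stop("Malformed JSON on cohort line ", i, ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    cases[[i]] <- validate_case(obj, line = i, lexicon = lexicon)
  }
  dplyr::bind_rows(cases)
}

validate_case <- function(obj, line = NA, lexicon = NULL) {
  where <- if (is.na(line)) "" else paste0(" (cohort line ", line, ")")
  for (f in c("case_id", "diagnosed_gene")) {
    if (is.null(obj[[f]]) || !nzchar(as.character(obj[[f]])[1])) {
      stop("Case is missing `", f, "`", where, call. = FALSE)
    }
  }
  terms <- obj$hpo_terms
  if (is.null(terms) || (is.data.frame(terms) && nrow(terms) == 0) ||
    (!is.data.frame(terms) && length(terms) == 0)) {
    terms <- tibble::tibble(id = character(0), label = character(0))
  } else {
    terms <- tibble::as_tibble(terms)
    if (!all(c("id", "label") %in% names(terms))) {
      stop("hpo_terms entries need `id` and `label`", where, call. = FALSE)
    }
    terms <- terms[, c("id", "label")]
  }
  free_text <- as.character(obj$free_text %||% "")[1]
  if (is.na(free_text)) free_text <- ""
  if (nrow(terms) == 0 && !nzchar(trimws(free_text))) {
    stop("Case has neither HPO terms nor free text", where, call. = FALSE)
  }
  gene <- as.character(obj$diagnosed_gene)[1]
  if (!is.null(lexicon)) {
    canon <- canonicalize(gene, lexicon)
    if (is.na(canon)) {
      stop("Diagnosed gene `", gene, "` does not canonicalize under the lexicon",
        where,
        call. = FALSE
      )
    }
    gene <- canon
  }
  tibble::tibble(
    case_id = as.character(obj$case_id)[1],
    source = as.character(obj$source %||% "unknown")[1],
    hpo_terms = list(terms),
    free_text = free_text,
    diagnosed_gene = gene
  )
}

#' Write a cohort tibble as JSON Lines
#'
#' Inverse of [load_cohort()]; emits one compact JSON object per case.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(seq_len(nrow(cohort)), function(i) {
    terms <- cohort$hpo_terms[[i]]
    jsonlite::toJSON(
      list(
        case_id = cohort$case_id[i],
        source = cohort$source[i],
        hpo_terms = terms,
        free_text = cohort$free_text[i],
        diagnosed_gene = cohort$diagnosed_gene[i]
      ),
      auto_unbox = TRUE, dataframe = "rows"
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Render a case's phenotype input
#'
#' For HPO input, joins the concept labels with `"; "` (the separator used
#' between HPO-based concept names in the prompt templates); for free-text
#' input, returns the narrative verbatim.
#'
#' @param case One-row cohort tibble (or a list with the same fields).
#' @param input_type `"hpo"` or `"free_text"`.
#' @return A single string.
#' @export
render_phenotype_list <- function(case, input_type = c("hpo", "free_text")) {
  input_type <- match.arg(input_type)
  if (input_type == "hpo") {
    terms <- if (is.data.frame(case)) case$hpo_terms[[1]] else case$hpo_terms
    if (is.null(terms) || nrow(terms) == 0) {
      stop("Case `", case$case_id, "` has no HPO terms", call. = FALSE)
    }
    paste(terms$label, collapse = "; ")
  } else {
    txt <- if (is.data.frame(case)) case$free_text[[1]] else case$free_text
    if (is.null(txt) || !nzchar(trimws(txt))) {
      stop("Case `", case$case_id, "` has no free-text narrative", call. = FALSE)
    }
    txt
  }
}
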