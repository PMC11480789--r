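DEFAULT_REFUSAL_PATTERNS <- c(
  "not applicable",
  "cannot provide",
  "can't provide",
  "i'm unable",
  "i am unable",
  "as an ai"
)

strip_markup <- function(text) {
  # markdown emphasis / code markup and list bullets carry no symbol content
  text <- gsub("[*`•]", " ", text)
  # list numbering at line starts: "1.", "2)", leading dashes
  text <- gsub("(?m)^\\s*\\d+[.)]\\s*", "", text, perl = TRUE)
  gsub("(?m)^\\s*-\\s+", "", text, perl = TRUE)
}

#' Extract symbol-shaped tokens from response text
#'
#' Returns, in order of appearance, maximal tokens matching the gene-symbol
#' shape (a letter followed by 1-9 letters, digits or hyphens) after
#' stripping markdown markup and list numbering. No stop-word filtering is
#' applied here: resolution against the lexicon is what separates genes
#' from prose.
#'
#' @param text Response text.
#' @return Character vector of tokens in order of appearance.
#' @export
extract_candidate_tokens <- function(text) {
  cleaned <- strip_markup(text)
  m <- gregexpr(paste0("\\b", SYMBOL_PATTERN, "\\b"), cleaned, perl = TRUE)
  unlist(regmatches(cleaned, m), use.names = FALSE)
}

#' Detect a refusal response
#'
#' A response counts as a refusal when it contains "not applicable"
#' (case-insensitive, with or without brackets — the literal fallback the
#' prompts request) or matches any phrase in a configurable declination
#' list (models also refuse in free prose, e.g. "as an AI ...").
#'
#' @param text Response text.
#' @param patterns Character vector of declination phrases (matched
#'   case-insensitively as fixed substrings).
#' @return Logical scalar.
#' @export
detect_refusal <- function(text, patterns = DEFAULT_REFUSAL_PATTERNS) {
  low <- tolower(text)
  any(vapply(patterns, function(p) grepl(p, low, fixed = TRUE), logical(1)))
}

#' Parse a raw model response into a structured prediction
#'
#' Tokens are extracted in order and canonicalized against the lexicon.
#' Resolvable tokens become the ordered gene list (duplicates dropped,
#' first occurrence kept); unresolvable tokens that are symbol-like (at
#' least 3 characters and either containing a digit or fully upper-case in
#' the source, the shape of family-extension hallucinations such as
#' `OPA50`) are recorded as fabricated. The gene list is not truncated at
#' `k` here — ranking cutoffs belong to the metric layer.
#'
#' @param text Raw response text.
#' @param lexicon A `gene_lexicon`.
#' @param refusal_patterns Passed to [detect_refusal()].
#' @return A `parsed_prediction`: list with `genes`, `fabricated`,
#'   `refusal`, `n_valid_unique`, `raw_text`.
#' @export
parse_response <- function(text, lexicon,
                           refusal_patterns = DEFAULT_REFUSAL_PATTERNS) {
  refusal <- detect_refusal(text, refusal_patterns)
  genes <- character(0)
  fabricated <- character(0)
  if (!refusal && nzchar(trimws(text))) {
    tokens <- extract_candidate_tokens(text)
    canon <- canonicalize(tokens, lexicon)
    genes <- unique(canon[!is.na(canon)])
    miss <- tokens[is.na(canon)]
    symbolish <- nchar(miss) >= 3 &
      (grepl("[0-9]", miss) | miss == toupper(miss))
    fabricated <- unique(toupper(miss[symbolish]))
  }
  structure(
    list(
      genes = genes,
      fabricated = fabricated,
      refusal = refusal,
      n_valid_unique = length(genes),
      raw_text = text
    ),
    class = "parsed_prediction"
  )
}

#' @export
print.parsed_prediction <- function(x, ...) {
  cat("<parsed_prediction> ", x$n_valid_unique, " valid genes",
    if (length(x$fabricated)) paste0(", ", length(x$fabricated), " fabricated"),
    if (x$refusal) ", refusal",
    "\n",
    sep = ""
  )
  if (x$n_valid_unique > 0) {
    cat("  genes: ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (x$n_valid_unique > 10) ", ...", "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Check output-structure compliance
#'
#' The prompts request gene symbols as a comma-separated list, or the
#' literal "not applicable". A response is compliant when it contains a
#' contiguous comma-separated run of at least `k` symbol-shaped tokens with
#' no interleaving prose (whitespace and markdown markup around the commas
#' are tolerated), or when it is a refusal. Compliance is judged on format
#' alone, independently of completeness or accuracy.
#'
#' @param text Response text.
#' @param k Requested list length.
#' @param refusal_patterns Passed to [detect_refusal()].
#' @return Logical scalar.
#' @export
check_structure_compliance <- function(text, k,
                                       refusal_patterns = DEFAULT_REFUSAL_PATTERNS) {
  if (detect_refusal(text, refusal_patterns)) {
    return(TRUE)
  }
  cleaned <- gsub("[*`]", "", text)
  run <- paste0(
    SYMBOL_PATTERN, "(\\s*,\\s*", SYMBOL_PATTERN, "){", k - 1L, ",}"
  )
  grepl(run, cleaned, perl = TRUE)
}
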