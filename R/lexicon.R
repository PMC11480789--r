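#' Load a gene-symbol lexicon
#'
#' Reads a tab-separated gene-symbol table in the HGNC complete-set dialect
#' and builds a resolver from any known symbol form (approved, previous or
#' alias) to the canonical approved symbol. An optional error-symbol list
#' blocks tokens that are known gene-name errors (the spreadsheet-conversion
#' families such as `SEPT1` or `MARCH1`) from ever resolving.
#'
#' The table must contain the columns `symbol`, `alias_symbol` and
#' `prev_symbol`; multi-valued cells are pipe-delimited (`"A|B"`). Rows whose
#' `symbol` is empty are skipped with a warning; duplicate approved symbols
#' are an error. All lookups are case-insensitive (tokens are upper-cased
#' before matching, as approved human gene symbols are upper-case).
#'
#' An alias that points to more than one approved symbol is recorded as
#' ambiguous and never resolves: crediting an ambiguous match would
#' overstate a model's accuracy.
#'
#' @param path Path to the lexicon TSV.
#' @param error_list_path Optional path to a plain-text blocklist, one token
#'   per line, `#` comments allowed. When `NULL`, the packaged default list
#'   of known gene-name errors is used. Pass `character(0)` via a file with
#'   no entries to disable screening.
#' @param version_tag Free-text provenance string stored on the lexicon.
#' @return A `gene_lexicon` object: a list with elements `approved`
#'   (character vector), `previous_map` and `alias_map` (named character
#'   vectors keyed by upper-cased token), `ambiguous_aliases`,
#'   `error_symbols` and `version_tag`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "symbol\talias_symbol\tprev_symbol",
#'   "DHX30\t\tDDX30",
#'   "TP53\tp53\t"
#' ), tsv)
#' lex <- load_lexicon(tsv)
#' canonicalize(c("DDX30", "p53", "OPA50"), lex)
#' @seealso [canonicalize()]
#' @export
load_lexicon <- function(path, error_list_path = NULL, version_tag = basename(path)) {
  if (!file.exists(path)) {
    stop("Cannot read lexicon file: ", path, call. = FALSE)
  }
  tab <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c("symbol", "alias_symbol", "prev_symbol")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(
      "Lexicon TSV is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if ("status" %in% names(tab)) {
    keep <- tab$status == "" | grepl("approved", tab$status, ignore.case = TRUE)
    tab <- tab[keep, , drop = FALSE]
  }
  blank <- is.na(tab$symbol) | trimws(tab$symbol) == ""
  if (any(blank)) {
    warning(sum(blank), " lexicon row(s) with empty `symbol` skipped", call. = FALSE)
    tab <- tab[!blank, , drop = FALSE]
  }
  approved <- toupper(trimws(tab$symbol))
  if (anyDuplicated(approved)) {
    stop(
      "Duplicate approved symbol(s) in lexicon: ",
      paste(unique(approved[duplicated(approved)]), collapse = ", "),
      call. = FALSE
    )
  }

  split_cell <- function(x) {
    vals <- toupper(trimws(unlist(strsplit(x, "|", fixed = TRUE))))
    vals[vals != ""]
  }
  expand_map <- function(cells) {
    keys <- lapply(cells, split_cell)
    n <- lengths(keys)
    tibble::tibble(token = unlist(keys), target = rep(approved, n))
  }

  prev <- expand_map(tab$prev_symbol)
  # a previous symbol reused by several genes is ambiguous, like an alias
  prev_counts <- table(prev$token)
  prev_ambig <- names(prev_counts)[prev_counts > 1]
  prev <- prev[!prev$token %in% prev_ambig, , drop = FALSE]
  previous_map <- stats::setNames(prev$target, prev$token)

  ali <- expand_map(tab$alias_symbol)
  ali_counts <- table(ali$token)
  ambiguous <- names(ali_counts)[ali_counts > 1]
  ali <- ali[!ali$token %in% ambiguous, , drop = FALSE]
  alias_map <- stats::setNames(ali$target, ali$token)

  if (is.null(error_list_path)) {
    error_list_path <- system.file("extdata", "gene_name_errors.txt",
      package = "genevalr"
    )
  }
  error_symbols <- read_error_symbols(error_list_path)

  structure(
    list(
      approved = approved,
      previous_map = previous_map,
      alias_map = alias_map,
      ambiguous_aliases = sort(unique(c(prev_ambig, ambiguous))),
      error_symbols = error_symbols,
      version_tag = version_tag
    ),
    class = "gene_lexicon"
  )
}

read_error_symbols <- function(path) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    return(character(0))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  sort(unique(lines[lines != ""]))
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat(
    "<gene_lexicon> ", length(x$approved), " approved symbols, ",
    length(x$previous_map), " previous, ", length(x$alias_map), " alias",
    " (", length(x$ambiguous_aliases), " ambiguous dropped), ",
    length(x$error_symbols), " blocked error symbols [", x$version_tag, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Canonicalize gene-symbol tokens
#'
#' Resolves free-text tokens to approved gene symbols. Matching is
#' case-insensitive. Tokens on the error-symbol blocklist never resolve,
#' even when the lexicon contains them; otherwise resolution precedence is
#' approved > previous > alias. Aliases pointing at several approved symbols
#' do not resolve. Canonicalization is idempotent: an approved symbol always
#' maps to itself.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon A `gene_lexicon` from [load_lexicon()].
#' @return Character vector the length of `tokens`: the approved symbol, or
#'   `NA` where the token is blocked, ambiguous or unrecognized.
#' @export
canonicalize <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  up <- toupper(trimws(as.character(tokens)))
  out <- rep(NA_character_, length(up))
  blocked <- up %in% lexicon$error_symbols
  is_approved <- !blocked & up %in% lexicon$approved
  out[is_approved] <- up[is_approved]
  todo <- !blocked & !is_approved
  hit_prev <- todo & up %in% names(lexicon$previous_map)
  out[hit_prev] <- unname(lexicon$previous_map[up[hit_prev]])
  todo <- todo & !hit_prev
  hit_alias <- todo & up %in% names(lexicon$alias_map)
  out[hit_alias] <- unname(lexicon$alias_map[up[hit_alias]])
  out
}
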