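#' Load HPO gene-phenotype annotation pairs
#'
#' Reads a tab-separated annotation file in the `genes_to_phenotype.txt`
#' dialect: a header (possibly `#`-prefixed) naming at least a gene-symbol
#' column, an HPO id column and an HPO name column. Pairs are deduplicated
#' preserving first-appearance order.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `gene`, `hpo_id`, `hpo_name`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("Cannot read annotation file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      gene = character(0), hpo_id = character(0), hpo_name = character(0)
    ))
  }
  # the header may carry a leading "#"
  lines[1] <- sub("^#\\s*", "", lines[1])
  lines <- c(lines[1], lines[-1][!startsWith(lines[-1], "#")])
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  norm <- gsub("[^a-z0-9]", "_", tolower(names(tab)))
  pick <- function(aliases, what) {
    idx <- which(norm %in% aliases)
    if (length(idx) == 0) {
      stop("Annotation TSV lacks a ", what, " column", call. = FALSE)
    }
    idx[1]
  }
  g <- pick(c("gene_symbol", "gene", "symbol"), "gene-symbol")
  hid <- pick(c("hpo_id", "hpo_term_id"), "HPO-id")
  hname <- pick(c("hpo_name", "hpo_term_name", "hpo_label"), "HPO-name")
  out <- tibble::tibble(
    gene = tab[[g]], hpo_id = tab[[hid]], hpo_name = tab[[hname]]
  )
  out <- out[stats::complete.cases(out), , drop = FALSE]
  dplyr::distinct(out)
}

#' Deterministic hashed bag-of-words embedder
#'
#' Maps a string to a fixed-dimension vector by lower-casing, tokenizing on
#' non-alphanumerics, hashing each token into one of `dim` buckets and
#' counting. Fully deterministic across sessions, which makes retrieval
#' tests reproducible; it is the packaged stand-in for the embedding slot
#' of the index. Live embedding services can be plugged in as any function
#' of one string returning a fixed-length numeric vector, carrying an
#' `embedder_id` attribute.
#'
#' @param dim Embedding dimension (default 1024; generous relative to
#'   realistic vocabulary sizes so bucket collisions stay rare).
#' @return A function `(text) -> numeric(dim)` with an `embedder_id`
#'   attribute.
#' @export
hash_embedder <- function(dim = 1024) {
  force(dim)
  f <- function(text) {
    tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    v <- numeric(dim)
    for (tok in tokens) {
      # scramble the rolling hash (multiply mod prime, then xor-fold) so
      # near-identical tokens, whose hashes differ by small multiples of
      # the hash base, do not land in the same bucket
      h <- string_hash(tok)
      h <- (h * 48271) %% 2147483647
      h <- bitwXor(h, bitwShiftR(h, 16))
      h <- bitwXor(h, bitwShiftR(h, 8))
      b <- (h %% dim) + 1L
      v[b] <- v[b] + 1
    }
    v
  }
  attr(f, "embedder_id") <- paste0("hash-bow-", dim)
  f
}

embedder_id <- function(embedder) {
  attr(embedder, "embedder_id") %||% "unidentified-embedder"
}

#' Build a gene-to-phenotype or phenotype-to-gene document index
#'
#' G2P direction: one document per gene, rendered as
#' `"The phenotypes associated with gene <g> include <p1, p2, ...>."`.
#' P2G direction: one document per phenotype, listing the genes annotated
#' to it. Lists preserve the annotation-file order. Every document is
#' embedded with the supplied embedder.
#'
#' @param pairs Annotation tibble from [load_annotations()] (or any table
#'   with `gene` and `hpo_name` columns).
#' @param direction `"G2P"` or `"P2G"`.
#' @param embedder Embedding function, e.g. [hash_embedder()].
#' @return A `rag_index`: list with `documents` (tibble: `doc_id`,
#'   `direction`, `subject`, `text`), `vectors` (documents x dim matrix),
#'   `embedder_id`, `dim`.
#' @export
build_index <- function(pairs, direction = c("G2P", "P2G"),
                        embedder = hash_embedder()) {
  direction <- match.arg(direction)
  if (nrow(pairs) == 0) {
    stop("Cannot build an index from zero annotation pairs", call. = FALSE)
  }
  if (direction == "G2P") {
    subjects <- unique(pairs$gene)
    texts <- vapply(subjects, function(g) {
      phen <- pairs$hpo_name[pairs$gene == g]
      paste0(
        "The phenotypes associated with gene ", g, " include ",
        paste(phen, collapse = ", "), "."
      )
    }, character(1))
  } else {
    subjects <- unique(pairs$hpo_name)
    texts <- vapply(subjects, function(p) {
      genes <- pairs$gene[pairs$hpo_name == p]
      paste0(
        "The genes associated with phenotype ", p, " include ",
        paste(genes, collapse = ", "), "."
      )
    }, character(1))
  }
  vecs <- lapply(texts, embedder)
  dims <- lengths(vecs)
  if (length(unique(dims)) != 1) {
    stop("Embedder returned vectors of differing dimension", call. = FALSE)
  }
  mat <- do.call(rbind, vecs)
  if (any(!is.finite(mat))) {
    stop("Embedder returned non-finite values", call. = FALSE)
  }
  docs <- tibble::tibble(
    doc_id = paste0(direction, ":", subjects),
    direction = direction,
    subject = subjects,
    text = unname(texts)
  )
  rownames(mat) <- docs$doc_id
  structure(
    list(
      documents = docs, vectors = mat,
      embedder_id = embedder_id(embedder), dim = ncol(mat)
    ),
    class = "rag_index"
  )
}

#' @export
print.rag_index <- function(x, ...) {
  cat("<rag_index> ", nrow(x$documents), " ",
    unique(x$documents$direction), " documents, dim ", x$dim,
    " [", x$embedder_id, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Retrieve the most similar documents for a query
#'
#' Ranks index documents by descending cosine similarity to the embedded
#' query; ties are broken by lexicographic `doc_id` so retrieval is fully
#' deterministic.
#'
#' @param query Query string (typically the rendered prompt).
#' @param index A `rag_index`.
#' @param top_k Number of documents to return (default 10, the retrieval
#'   depth used for prompt augmentation); capped at the corpus size.
#' @param embedder The same embedder the index was built with.
#' @return The `documents` tibble rows in rank order, with a `similarity`
#'   column.
#' @export
retrieve <- function(query, index, top_k = 10, embedder = hash_embedder()) {
  stopifnot(inherits(index, "rag_index"))
  if (!identical(embedder_id(embedder), index$embedder_id)) {
    stop(
      "Embedder mismatch: index built with `", index$embedder_id,
      "`, query embedded with `", embedder_id(embedder), "`",
      call. = FALSE
    )
  }
  q <- embedder(query)
  if (length(q) != index$dim) {
    stop("Query embedding dimension ", length(q), " != index dim ", index$dim,
      call. = FALSE
    )
  }
  qn <- sqrt(sum(q^2))
  dn <- sqrt(rowSums(index$vectors^2))
  sims <- if (qn == 0) {
    rep(0, nrow(index$vectors))
  } else {
    as.numeric(index$vectors %*% q) / ifelse(dn == 0, Inf, dn * qn)
  }
  ord <- order(-sims, index$documents$doc_id)
  take <- utils::head(ord, min(top_k, length(ord)))
  out <- index$documents[take, , drop = FALSE]
  out$similarity <- sims[take]
  out
}

#' Prefix a prompt with retrieved context documents
#'
#' Assembles the augmented prompt: a delimited `Context:` block listing the
#' retrieved document texts in rank order, followed by the base prompt.
#' With zero documents the base prompt is returned unchanged with a
#' warning.
#'
#' @param base_prompt The rendered prompt string.
#' @param docs Ranked documents from [retrieve()].
#' @return The augmented prompt string.
#' @export
augment_prompt <- function(base_prompt, docs) {
  if (is.null(docs) || nrow(docs) == 0) {
    warning("No context documents retrieved; prompt left unaugmented",
      call. = FALSE
    )
    return(base_prompt)
  }
  paste0(
    "Context:\n",
    paste0("- ", docs$text, collapse = "\n"),
    "\n\n",
    base_prompt
  )
}
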