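# Synthetic study-condition generators: a gene-phenotype map, a cohort
# emulating the evaluation datasets (11-35 HPO terms per case, one
# diagnosed gene drawn from a ~165-gene pool with a skewed occurrence
# distribution), a matching symbol lexicon, and publication counts.

#' Generate a synthetic gene-phenotype annotation map
#'
#' Creates `n_genes` synthetic gene symbols (`GENE001`, ...) each annotated
#' with `phenotypes_per_gene` phenotype labels. With `overlap = 0` the
#' label sets are disjoint; a positive overlap fraction draws that share of
#' each gene's labels from a common pool, emulating phenotypically related
#' genes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param phenotypes_per_gene Labels per gene.
#' @param overlap Fraction of each gene's labels drawn from a shared pool.
#' @param seed Seed for reproducibility.
#' @return Tibble with columns `gene`, `hpo_id`, `hpo_name` (the annotation
#'   pair table consumed by [build_index()] and [write_annotations()]).
#' @export
generate_gene_phenotype_map <- function(n_genes = 165, phenotypes_per_gene = 20,
                                        overlap = 0, seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  stopifnot(phenotypes_per_gene >= 1, overlap >= 0, overlap <= 1)
  with_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    n_shared <- ceiling(overlap * phenotypes_per_gene)
    n_own <- phenotypes_per_gene - n_shared
    shared_pool <- sprintf("shared phenotype %03d", seq_len(max(1, 3 * n_shared)))
    rows <- lapply(seq_len(n_genes), function(i) {
      own <- sprintf("phenotype %03d %02d", i, seq_len(n_own))
      labels <- c(own, if (n_shared > 0) sample(shared_pool, n_shared))
      tibble::tibble(gene = genes[i], hpo_name = labels)
    })
    map <- dplyr::bind_rows(rows)
    map$hpo_id <- sprintf("HP:%07d", match(map$hpo_name, unique(map$hpo_name)))
    map[, c("gene", "hpo_id", "hpo_name")]
  })
}

#' Write an annotation map in the genes_to_phenotype.txt dialect
#'
#' @param map Annotation tibble (`gene`, `hpo_id`, `hpo_name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(map, path) {
  header <- "#gene_symbol\thpo_id\thpo_name"
  body <- paste(map$gene, map$hpo_id, map$hpo_name, sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Generate a synthetic symbol lexicon for a gene set
#'
#' Gives a fraction of genes an alias symbol (`<symbol>X`) and a fraction a
#' previous symbol (`<symbol>P`), so canonicalization of non-approved forms
#' is exercised end to end.
#'
#' @param genes Character vector of approved symbols.
#' @param alias_fraction,previous_fraction Fractions of genes receiving an
#'   alias / a previous symbol.
#' @param path Optional path; when given, the lexicon TSV is written there.
#' @param seed Seed.
#' @return Tibble with columns `symbol`, `alias_symbol`, `prev_symbol`.
#' @export
generate_lexicon <- function(genes, alias_fraction = 0.2,
                             previous_fraction = 0.1, path = NULL, seed = 1) {
  with_seed(seed, {
    n <- length(genes)
    alias <- rep("", n)
    prev <- rep("", n)
    a_idx <- sample.int(n, round(alias_fraction * n))
    p_idx <- sample.int(n, round(previous_fraction * n))
    alias[a_idx] <- paste0(genes[a_idx], "X")
    prev[p_idx] <- paste0(genes[p_idx], "P")
    tab <- tibble::tibble(
      symbol = genes, alias_symbol = alias, prev_symbol = prev
    )
    if (!is.null(path)) {
      readr::write_tsv(tab, path, progress = FALSE)
    }
    tab
  })
}

#' Generate a synthetic evaluation cohort
#'
#' Each case draws a diagnosed gene from the map's gene pool and a set of
#' phenotype terms: the term count is a rounded normal draw (clipped to at
#' least 1) emulating the per-source HPO-term counts of real curated
#' cohorts, and a `noise_rate` share of terms comes from other genes'
#' annotations rather than the diagnosed gene's own. When the cohort is at
#' least as large as the pool, every pool gene receives one case and the
#' remainder are assigned with skewed weights (a few recurrent genes, a
#' long tail of near-singletons), mirroring how diagnosed genes recur in
#' real multi-source cohorts. A templated free-text narrative is rendered
#' from the same terms so the HPO and free-text input modalities share
#' ground truth.
#'
#' @param map Annotation tibble from [generate_gene_phenotype_map()].
#' @param n_cases Number of cases (default 276).
#' @param terms_mean,terms_sd Normal parameters for the per-case term count
#'   (defaults 12 and 6).
#' @param noise_rate Expected fraction of off-gene noise terms.
#' @param pool_weights Optional numeric weights over the pool genes;
#'   default is a `1/sqrt(rank)` skew.
#' @param seed Seed.
#' @return Cohort tibble as returned by [load_cohort()].
#' @export
generate_cohort <- function(map, n_cases = 276, terms_mean = 12, terms_sd = 6,
                            noise_rate = 0.1, pool_weights = NULL, seed = 1) {
  if (nrow(map) == 0) stop("Annotation map is empty", call. = FALSE)
  with_seed(seed, {
    pool <- unique(map$gene)
    np <- length(pool)
    if (is.null(pool_weights)) {
      pool_weights <- 1 / sqrt(seq_len(np))
    }
    stopifnot(length(pool_weights) == np)
    diagnosed <- if (n_cases >= np) {
      sample(c(
        pool,
        sample(pool, n_cases - np, replace = TRUE, prob = pool_weights)
      ))
    } else {
      sample(pool, n_cases, prob = pool_weights)
    }
    by_gene <- split(map$hpo_name, map$gene)
    term_ids <- stats::setNames(map$hpo_id, map$hpo_name)
    cases <- lapply(seq_len(n_cases), function(i) {
      gene <- diagnosed[i]
      own <- by_gene[[gene]]
      other <- map$hpo_name[map$gene != gene]
      n_terms <- max(1L, round(stats::rnorm(1, terms_mean, terms_sd)))
      n_noise <- stats::rbinom(1, n_terms, noise_rate)
      n_own <- min(n_terms - n_noise, length(own))
      labels <- c(
        sample(own, n_own),
        if (n_noise > 0 && length(other) > 0) {
          sample(other, min(n_noise, length(other)))
        }
      )
      labels <- sample(unique(labels))
      narrative <- paste0(
        "The patient presents with ",
        if (length(labels) > 1) {
          paste0(
            paste(labels[-length(labels)], collapse = ", "),
            " and ", labels[length(labels)]
          )
        } else {
          labels
        },
        "."
      )
      tibble::tibble(
        case_id = sprintf("case_%04d", i),
        source = "synthetic",
        hpo_terms = list(tibble::tibble(
          id = unname(term_ids[labels]), label = labels
        )),
        free_text = narrative,
        diagnosed_gene = gene
      )
    })
    dplyr::bind_rows(cases)
  })
}

#' Generate synthetic publication counts
#'
#' Log-normal counts spanning a few orders of magnitude, the shape of
#' literature attention across disease genes.
#'
#' @param genes Character vector of gene symbols.
#' @param meanlog,sdlog Log-normal parameters on the natural-log scale
#'   (defaults centred near 10^4 with roughly 1.5 decades of spread).
#' @param seed Seed.
#' @return Tibble with columns `gene`, `count`.
#' @export
generate_citations <- function(genes, meanlog = log(1e4), sdlog = 1.5, seed = 1) {
  with_seed(seed, {
    tibble::tibble(
      gene = genes,
      count = pmax(1, round(stats::rlnorm(length(genes), meanlog, sdlog)))
    )
  })
}
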