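# Shared fixtures, built in code at test time.

# A small hand-written lexicon covering the canonicalization cases that
# matter: a previous symbol (DDX30 -> DHX30), aliases (ABC1 -> ABCA1,
# p53 -> TP53), a blocked error symbol present as an alias (SEPT1), and an
# alias shared by two genes (ambiguous).
fixture_lexicon_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "symbol\talias_symbol\tprev_symbol",
    "DHX30\t\tDDX30",
    "TP53\tp53|LFS1\t",
    "ABCA1\tABC1\t",
    "OPA1\tNTG|NPG\t",
    "BRCA1\t\t",
    "BRCA2\tFANCD1\t",
    "PTEN\tMMAC1\t",
    "SCN1A\t\t",
    "KCNQ2\tEBN1\t",
    "MECP2\t\t",
    "SEPTIN1\tSEPT1\t",
    "AMBIG1\tSHAREDALIAS\t",
    "AMBIG2\tSHAREDALIAS\t"
  ), path)
  path
}

fixture_lexicon <- function() {
  load_lexicon(fixture_lexicon_tsv())
}

fixture_case <- function(labels = c("seizure", "hypotonia"),
                         diagnosed_gene = "SCN1A",
                         free_text = "The patient presents with seizures.",
                         case_id = "case_0001") {
  tibble::tibble(
    case_id = case_id,
    source = "fixture",
    hpo_terms = list(tibble::tibble(
      id = sprintf("HP:%07d", seq_along(labels)),
      label = labels
    )),
    free_text = free_text,
    diagnosed_gene = diagnosed_gene
  )
}

# A synthetic study world shared by integration-style tests: gene-phenotype
# map, matching lexicon on disk, and a cohort.
fixture_world <- function(n_genes = 20, n_cases = 30, seed = 42) {
  map <- generate_gene_phenotype_map(
    n_genes = n_genes,
    phenotypes_per_gene = 5, seed = seed
  )
  lex_path <- tempfile(fileext = ".tsv")
  generate_lexicon(unique(map$gene), path = lex_path, seed = seed)
  lexicon <- load_lexicon(lex_path)
  cohort <- generate_cohort(map, n_cases = n_cases, seed = seed)
  list(map = map, lexicon = lexicon, cohort = cohort)
}

# Outcome records for M cases x T iterations built directly from indicator
# values (scalars recycle; matrices are laid out cases x iterations).
make_records <- function(M, T = 1, complete = 0, accurate = 0, compliant = 0,
                         experiment_id = "exp") {
  grid <- expand.grid(case = seq_len(M), iteration = seq_len(T))
  val <- function(x) as.integer(rep_len(as.vector(x), M * T))
  tibble::tibble(
    experiment_id = experiment_id,
    case_id = sprintf("case_%04d", grid$case),
    iteration = as.integer(grid$iteration),
    complete = val(complete),
    accurate = val(accurate),
    compliant = val(compliant)
  )
}
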