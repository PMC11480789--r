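test_that("gene-phenotype maps have the requested cardinality and determinism", {
  map <- generate_gene_phenotype_map(n_genes = 5, phenotypes_per_gene = 4, seed = 3)
  expect_equal(nrow(map), 20)
  expect_equal(length(unique(map$gene)), 5)
  expect_error(generate_gene_phenotype_map(n_genes = 0), "n_genes")

  f1 <- tempfile()
  f2 <- tempfile()
  write_annotations(map, f1)
  write_annotations(
    generate_gene_phenotype_map(n_genes = 5, phenotypes_per_gene = 4, seed = 3),
    f2
  )
  expect_identical(readLines(f1), readLines(f2))

  shared <- generate_gene_phenotype_map(
    n_genes = 10, phenotypes_per_gene = 4, overlap = 0.5, seed = 3
  )
  expect_lt(length(unique(shared$hpo_name)), 40)
})

test_that("synthetic lexica resolve their alias and previous forms", {
  genes <- sprintf("GENE%03d", 1:20)
  path <- tempfile(fileext = ".tsv")
  tab <- generate_lexicon(genes, path = path, seed = 1)
  lex <- load_lexicon(path)
  expect_setequal(lex$approved, genes)
  aliases <- tab$alias_symbol[tab$alias_symbol != ""]
  expect_gt(length(aliases), 0)
  expect_true(all(canonicalize(aliases, lex) %in% genes))
})

test_that("synthetic cohorts honour size, noise and seed contracts", {
  map <- generate_gene_phenotype_map(n_genes = 12, phenotypes_per_gene = 6)
  cohort <- generate_cohort(map, n_cases = 40, seed = 9)
  expect_equal(nrow(cohort), 40)
  # every pool gene is diagnosed at least once when cases outnumber the pool
  expect_setequal(unique(cohort$diagnosed_gene), unique(map$gene))
  # reproducibility
  again <- generate_cohort(map, n_cases = 40, seed = 9)
  expect_identical(cohort$diagnosed_gene, again$diagnosed_gene)
  expect_identical(cohort$hpo_terms[[17]], again$hpo_terms[[17]])

  # zero noise: every term belongs to the diagnosed gene's annotation set
  clean <- generate_cohort(map, n_cases = 20, noise_rate = 0, seed = 5)
  for (i in seq_len(20)) {
    own <- map$hpo_name[map$gene == clean$diagnosed_gene[i]]
    expect_true(all(clean$hpo_terms[[i]]$label %in% own))
  }
  # narratives are rendered from the same terms
  expect_true(all(grepl("^The patient presents with ", clean$free_text)))
})

test_that("responder parameters are validated", {
  expect_error(responder_params(p_complete = 1.2), "\\[0, 1\\]")
  expect_error(responder_params(gamma = -1), "gamma")
  expect_error(
    responder_params(citation_weights = c(1, 2)),
    "named"
  )
  expect_s3_class(responder_params(), "responder_params")
})

test_that("degenerate responder settings produce the forced outputs", {
  world <- fixture_world(n_genes = 30, n_cases = 5)
  case <- world$cohort[1, ]
  set.seed(1)
  expect_identical(
    simulate_response(case, responder_params(p_refuse = 1), 10, world$lexicon),
    "not applicable"
  )
  # guaranteed hit at rank 1, clean format, nothing fabricated
  params <- responder_params(
    p_complete = 1, p_refuse = 0, p_hit = 1, hit_rank_q = 1,
    p_fabricate = 0, p_comply = 1, p_duplicate = 0
  )
  set.seed(2)
  text <- simulate_response(case, params, 10, world$lexicon)
  pred <- parse_response(text, world$lexicon)
  expect_identical(pred$genes[1], case$diagnosed_gene)
  expect_equal(pred$n_valid_unique, 10)
  expect_true(check_structure_compliance(text, 10))
})

test_that("clean un-fabricated responses round-trip through the parser", {
  world <- fixture_world(n_genes = 40, n_cases = 10)
  params <- responder_params(
    p_complete = 1, p_refuse = 0, p_hit = 0.5, p_fabricate = 0,
    p_comply = 1, p_duplicate = 0
  )
  set.seed(31)
  for (i in 1:10) {
    text <- simulate_response(world$cohort[i, ], params, 10, world$lexicon)
    emitted <- strsplit(text, ", ", fixed = TRUE)[[1]]
    pred <- parse_response(text, world$lexicon)
    expect_identical(pred$genes, unique(emitted))
  }
})

test_that("fabricated slots are symbol-shaped and unresolvable", {
  world <- fixture_world(n_genes = 40, n_cases = 5)
  params <- responder_params(
    p_complete = 1, p_refuse = 0, p_hit = 0, p_fabricate = 1,
    p_comply = 1, p_duplicate = 0
  )
  set.seed(8)
  text <- simulate_response(world$cohort[1, ], params, 10, world$lexicon)
  pred <- parse_response(text, world$lexicon)
  expect_equal(pred$n_valid_unique, 0)
  expect_equal(length(pred$fabricated), 10)
  expect_true(all(is.na(canonicalize(pred$fabricated, world$lexicon))))
})

test_that("the error surfaces when fillers run out and fabrication is off", {
  world <- fixture_world(n_genes = 5, n_cases = 3)
  params <- responder_params(
    p_complete = 1, p_refuse = 0, p_hit = 0, p_fabricate = 0, p_comply = 1
  )
  set.seed(4)
  expect_error(
    simulate_response(world$cohort[1, ], params, 10, world$lexicon),
    "filler genes"
  )
})

test_that("simulated citations span orders of magnitude reproducibly", {
  genes <- sprintf("GENE%03d", 1:50)
  c1 <- generate_citations(genes, seed = 2)
  c2 <- generate_citations(genes, seed = 2)
  expect_identical(c1, c2)
  expect_true(all(c1$count >= 1))
  expect_gt(max(log10(c1$count)) - min(log10(c1$count)), 1)
})
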