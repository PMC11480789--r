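pred_of <- function(genes, lexicon = NULL) {
  structure(
    list(
      genes = genes, fabricated = character(0), refusal = FALSE,
      n_valid_unique = length(genes), raw_text = paste(genes, collapse = ", ")
    ),
    class = "parsed_prediction"
  )
}

test_that("prediction counts tally one appearance per experiment", {
  preds <- c(
    replicate(3, pred_of(c("TP53", "BRCA1")), simplify = FALSE),
    replicate(7, pred_of("BRCA1"), simplify = FALSE)
  )
  counts <- prediction_counts(preds, k = 10)
  expect_equal(counts$observed[counts$gene == "TP53"], 3)
  expect_equal(counts$observed[counts$gene == "BRCA1"], 10)
  expect_false("PTEN" %in% counts$gene)
  # ranks beyond k are invisible
  deep <- list(pred_of(c(sprintf("F%02d", 1:10), "TP53")))
  expect_false("TP53" %in% prediction_counts(deep, k = 10)$gene)
})

test_that("expected counts follow the pool-frequency slot-filling null", {
  single <- tibble::tibble(diagnosed_gene = rep("TP53", 4))
  e <- expected_counts(single, n_experiments = 10, k = 10)
  expect_equal(e$expected, 100)

  two <- tibble::tibble(diagnosed_gene = c(rep("A", 3), "B"))
  e2 <- expected_counts(two, n_experiments = 4, k = 10)
  expect_equal(e2$expected[e2$gene == "A"], 30)
  expect_equal(e2$expected[e2$gene == "B"], 10)

  u <- expected_counts(two, n_experiments = 4, k = 10, null_model = "uniform_pool")
  expect_equal(u$expected, c(20, 20))
  expect_error(expected_counts(two[0, ], 4, 10), "empty")
})

test_that("odds ratios divide observed by expected with the zero convention", {
  observed <- tibble::tibble(gene = c("A", "C"), observed = c(30L, 5L))
  expected <- tibble::tibble(
    gene = c("A", "B"), pool_occurrences = c(3L, 1L), expected = c(30, 10)
  )
  rows <- odds_ratios(observed, expected)
  expect_equal(rows$odds_ratio[rows$gene == "A"], 1)
  # pool gene never predicted: OR = 0
  expect_equal(rows$observed[rows$gene == "B"], 0)
  expect_equal(rows$odds_ratio[rows$gene == "B"], 0)
  # predicted gene outside the pool: no expectation, missing OR
  expect_false(rows$in_diagnosed_pool[rows$gene == "C"])
  expect_true(is.na(rows$odds_ratio[rows$gene == "C"]))

  np <- never_predicted(rows)
  expect_identical(np$genes, "B")
  expect_equal(np$count, 1)
})

test_that("never-predicted genes partition the pool", {
  rows <- odds_ratios(
    tibble::tibble(gene = c("A", "B"), observed = c(2L, 1L)),
    tibble::tibble(
      gene = c("A", "B", "C", "D"),
      pool_occurrences = 1L, expected = 2.5
    )
  )
  np <- never_predicted(rows)
  expect_setequal(np$genes, c("C", "D"))
  pool <- rows$gene[rows$in_diagnosed_pool]
  predicted <- rows$gene[rows$in_diagnosed_pool & rows$odds_ratio > 0]
  expect_setequal(c(np$genes, predicted), pool)
})

test_that("citation correlation detects constructed monotone structure", {
  n <- 100
  logc <- seq(2, 6, length.out = n)
  rows <- tibble::tibble(
    gene = sprintf("G%03d", 1:n), observed = 1L, expected = 1,
    odds_ratio = 0.1 + 0.5 * (logc - 2), in_diagnosed_pool = TRUE,
    pool_occurrences = 1L
  )
  citations <- stats::setNames(10^logc, rows$gene)
  res <- citation_correlation(rows, citations)
  expect_gt(res$correlation, 0.9)
  expect_equal(nrow(res$groups), 4)
  # the grouped means rise across the four log-count bins
  expect_true(all(diff(res$groups$mean_odds_ratio) > 0))

  # permuted citations carry no signal for most seeds
  set.seed(5)
  hits <- vapply(1:20, function(i) {
    shuffled <- stats::setNames(sample(citations), rows$gene)
    abs(citation_correlation(rows, shuffled)$correlation)
  }, numeric(1))
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("degenerate citation inputs are flagged", {
  rows <- tibble::tibble(
    gene = c("A", "B"), observed = 1L, expected = 1,
    odds_ratio = c(1, 2), in_diagnosed_pool = TRUE, pool_occurrences = 1L
  )
  res <- citation_correlation(rows, c(A = 100, B = 1000))
  expect_true(res$low_n)
  expect_false(is.na(res$correlation))
  # constant odds ratios have no defined correlation
  rows$odds_ratio <- 1
  expect_warning(
    res2 <- citation_correlation(rows, c(A = 100, B = 1000)),
    "undefined"
  )
  expect_true(is.na(res2$correlation))
  # citation table form is accepted
  tab <- tibble::tibble(gene = c("A", "B"), count = c(100, 1000))
  rows$odds_ratio <- c(1, 2)
  expect_equal(citation_correlation(rows, tab)$n, 2)
})

test_that("stability tallies discordant iteration triplets", {
  rec <- dplyr::bind_rows(
    make_records(1, T = 3, complete = matrix(c(1, 1, 1), 1), experiment_id = "concordant"),
    make_records(1, T = 3, complete = matrix(c(1, 0, 1), 1), experiment_id = "discordant")
  )
  s <- stability_summary(rec)
  expect_equal(s$n_experiments, 2)
  expect_equal(s$n_discordant_completion, 1)
  expect_equal(s$n_discordant_accuracy, 0)
  expect_error(stability_summary(make_records(3, T = 1)), "at least 2")
})

test_that("cross-session mode pairs runs and lists missing experiments", {
  s1 <- make_records(4, T = 3, complete = rep(c(1, 0), 6))
  s2 <- s1
  s2$complete[1] <- 1 - s2$complete[1]
  res <- stability_summary(s1, session2 = s2)
  comp <- res$cross_session[res$cross_session$metric == "completion", ]
  expect_equal(comp$n_same, 3)
  expect_equal(comp$n_changed, 1)
  expect_error(stability_summary(s1, session2 = s2[s2$case_id != "case_0002", ]),
    "case_0002"
  )
})
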