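test_that("factorial grids have the advertised cardinalities", {
  gpt <- build_grid(models = c("model-a", "model-b"))
  expect_equal(nrow(gpt), 32)
  expect_equal(anyDuplicated(gpt$experiment_id), 0)

  llama <- build_grid(
    models = c("m-7b", "m-13b", "m-70b"),
    templates = "original_role_instruction"
  )
  expect_equal(nrow(llama), 12)

  one <- build_grid("m", "original", "hpo", 10)
  expect_equal(nrow(one), 1)
  expect_error(build_grid(character(0)), "factor")
})

test_that("order permutation is a reproducible bijection", {
  grid <- build_grid("m", c("original", "original_role"), ks = 10)
  ids <- sprintf("case_%02d", 1:7)
  o1 <- permute_order(grid, ids, seed = 5)
  o2 <- permute_order(grid, ids, seed = 5)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), nrow(grid) * 7)
  keys <- paste(o1$experiment_id, o1$case_id)
  expect_equal(anyDuplicated(keys), 0)
  o3 <- permute_order(grid, ids, seed = 6)
  expect_false(identical(o1$case_id, o3$case_id))
})

test_that("grid runs record every call and resume idempotently", {
  world <- fixture_world(n_genes = 20, n_cases = 2)
  grid <- build_grid("sim", "original", "hpo", 10)
  backend <- simulated_backend(world$lexicon, responder_params(), seed = 11)
  log_path <- tempfile(fileext = ".jsonl")
  run1 <- run_grid(grid, world$cohort, backend,
    iterations = 3,
    out_path = log_path
  )
  expect_equal(nrow(run1), 6)
  expect_equal(length(readLines(log_path)), 6)
  # rerunning over the complete log adds nothing
  run2 <- run_grid(grid, world$cohort, backend,
    iterations = 3,
    out_path = log_path
  )
  expect_equal(nrow(run2), 6)
  expect_equal(length(readLines(log_path)), 6)
  # responses are derived from (seed, experiment, case, iteration): a fresh
  # run elsewhere reproduces the same response fields
  run3 <- run_grid(grid, world$cohort, backend, iterations = 3)
  expect_identical(
    dplyr::arrange(run3, case_id, iteration)$response,
    dplyr::arrange(run1, case_id, iteration)$response
  )
})

test_that("backend failures are retried then recorded, not fatal", {
  world <- fixture_world(n_genes = 20, n_cases = 1)
  grid <- build_grid("sim", "original", "hpo", 10)
  calls <- new.env()
  calls$n <- 0
  flaky <- function(prompt, case, config, iteration) {
    calls$n <- calls$n + 1
    if (calls$n %% 2 == 1) stop("transient outage")
    "GENE001, GENE002"
  }
  out <- run_grid(grid, world$cohort, flaky, iterations = 2, retries = 2)
  expect_equal(nrow(out), 2)
  expect_true(all(!is.na(out$response)))

  dead <- function(prompt, case, config, iteration) stop("service down")
  out2 <- run_grid(grid, world$cohort, dead, iterations = 2, retries = 2)
  expect_equal(nrow(out2), 2)
  expect_true(all(is.na(out2$response)))
  expect_true(all(grepl("service down", out2$error)))
})

test_that("scoring an all-refusal log gives the forced metric values", {
  world <- fixture_world(n_genes = 20, n_cases = 4)
  grid <- build_grid("sim", "original", "hpo", 10)
  backend <- simulated_backend(
    world$lexicon, responder_params(p_refuse = 1),
    seed = 1
  )
  responses <- run_grid(grid, world$cohort, backend, iterations = 3)
  scored <- score_responses(responses, grid, world$cohort, world$lexicon,
    B = 50, seed = 2
  )
  s <- scored$summaries
  expect_equal(s$mean_rate[s$metric == "completeness"], 0)
  expect_equal(s$mean_rate[s$metric == "accuracy_overall"], 0)
  expect_equal(s$mean_rate[s$metric == "compliance"], 1)
  expect_true(is.na(s$mean_rate[s$metric == "accuracy_completed"]) ||
    is.nan(s$mean_rate[s$metric == "accuracy_completed"]))
})

test_that("a perfect responder scores 1.0 on all four metrics", {
  world <- fixture_world(n_genes = 20, n_cases = 4)
  grid <- build_grid("sim", "original", "hpo", 10)
  perfect <- responder_params(
    p_complete = 1, p_refuse = 0, p_hit = 1, hit_rank_q = 1,
    p_fabricate = 0, p_comply = 1, p_duplicate = 0
  )
  backend <- simulated_backend(world$lexicon, perfect, seed = 1)
  responses <- run_grid(grid, world$cohort, backend, iterations = 3)
  scored <- score_responses(responses, grid, world$cohort, world$lexicon,
    B = 50, seed = 2
  )
  expect_true(all(scored$summaries$mean_rate == 1))
})

test_that("re-scoring the same log reproduces the same reports", {
  world <- fixture_world(n_genes = 20, n_cases = 3)
  grid <- build_grid("sim", "original", "hpo", 10)
  backend <- simulated_backend(world$lexicon, responder_params(), seed = 3)
  responses <- run_grid(grid, world$cohort, backend, iterations = 3)
  a <- score_responses(responses, grid, world$cohort, world$lexicon, seed = 9)
  b <- score_responses(responses, grid, world$cohort, world$lexicon, seed = 9)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$summaries$ci_low, b$summaries$ci_low)
})

test_that("orphan records are rejected with their identifiers", {
  world <- fixture_world(n_genes = 20, n_cases = 2)
  grid <- build_grid("sim", "original", "hpo", 10)
  backend <- simulated_backend(world$lexicon, responder_params(), seed = 1)
  responses <- run_grid(grid, world$cohort, backend, iterations = 1)
  responses$case_id[1] <- "case_9999"
  expect_error(
    score_responses(responses, grid, world$cohort, world$lexicon),
    "case_9999"
  )
})

test_that("the metrics report CSV carries the config factors", {
  world <- fixture_world(n_genes = 20, n_cases = 3)
  grid <- build_grid("sim", c("original", "original_role"), "hpo", 10)
  backend <- simulated_backend(world$lexicon, responder_params(), seed = 4)
  responses <- run_grid(grid, world$cohort, backend, iterations = 2)
  scored <- score_responses(responses, grid, world$cohort, world$lexicon,
    B = 20, seed = 1
  )
  path <- tempfile(fileext = ".csv")
  report <- write_metrics_report(scored$summaries, grid, scored$outcomes, path)
  expect_true(file.exists(path))
  expect_setequal(
    names(report),
    c(
      "experiment_id", "model_id", "template", "input_type", "k", "metric",
      "mean_rate", "ci_low", "ci_high", "n_cases", "n_completed"
    )
  )
  expect_equal(nrow(report), 2 * 4)
})
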