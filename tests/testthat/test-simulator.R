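test_that("design defaults and counterbalancing strata are as documented", {
  d <- experiment_design()
  expect_equal(d$n_e2n, 30L)
  expect_equal(d$n_p2p, 32L)
  strata <- design_strata(experiment_design(31, 32))
  # odd condition: the extra participant learns the expert variant first
  expect_equal(strata$n[strata$context == "expert_to_novice"], c(16L, 15L))
  expect_equal(strata$n[strata$context == "peer_to_peer"], c(16L, 16L))
  expect_error(experiment_design(-1, 10), "non-negative")
})

test_that("count tables validate cells and canonicalize row order", {
  tbl <- count_table(27, 3, 14, 18)
  expect_s3_class(tbl, "count_table")
  expect_equal(tbl$count, c(27L, 3L, 14L, 18L))
  # shuffled input canonicalizes to the same table
  shuffled <- as_count_table(tibble::as_tibble(tbl)[c(3, 1, 4, 2), ])
  expect_equal(shuffled$count, tbl$count)
  expect_error(as_count_table(tibble::as_tibble(tbl)[-1, ]), "4 distinct cells")
  expect_error(count_table(-1, 3, 14, 18), "non-negative")
  tbl8 <- count_table_8(c(12, 13, 2, 3, 4, 7, 9, 12))
  expect_equal(sum(tbl8$count), 62)
})

test_that("match predicate applies a per-cell tolerance", {
  obs <- paper_counts()
  expect_true(is_match(count_table(27, 3, 14, 18), obs, tolerance = 0))
  expect_false(is_match(count_table(26, 4, 14, 18), obs, tolerance = 0))
  expect_true(is_match(count_table(26, 4, 14, 18), obs, tolerance = 1))
  expect_false(is_match(count_table(25, 5, 14, 18), obs, tolerance = 1))
  expect_error(
    is_match(count_table_8(rep(0, 8)), obs),
    "different layouts"
  )
})

test_that("degenerate bias values produce deterministic tables", {
  all_expert <- simulate_experiment(bias_params(1, 0, 0), seed = 1)
  expect_equal(all_expert$count, c(30L, 0L, 32L, 0L))
  all_peer <- simulate_experiment(bias_params(-1, 0, 0), seed = 1)
  expect_equal(all_peer$count, c(0L, 30L, 0L, 32L))
})

test_that("every simulated table conserves the per-context totals", {
  set.seed(11)
  for (i in 1:20) {
    p <- bias_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
    for (layout in c("four_cell", "eight_cell")) {
      tbl <- simulate_experiment(p, experiment_design(31, 32), layout)
      expect_equal(
        unname(transbias:::context_totals(tbl)), c(31L, 32L)
      )
    }
  }
})

test_that("unbiased participants split evenly, within binomial error", {
  set.seed(5)
  draws <- vapply(1:10000, function(i) {
    v <- variant_pair("first")
    out <- simulate_participant(bias_params(0, 0, 0), "peer_to_peer",
      list(v$expert, v$peer))
    out$source == "expert"
  }, logical(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("seeded simulation is reproducible", {
  p <- bias_params(0.3, -0.2, 0.1)
  a <- simulate_experiment(p, layout = "eight_cell", seed = 99)
  b <- simulate_experiment(p, layout = "eight_cell", seed = 99)
  expect_identical(a, b)
  g1 <- run_grid(paper_counts(), spec = tiny_grid_spec(s = 100), seed = 7)
  g2 <- run_grid(paper_counts(), spec = tiny_grid_spec(s = 100), seed = 7)
  expect_identical(g1$matches, g2$matches)
})

test_that("batch simulation means match the binomial expectation", {
  batch <- simulate_counts_batch(bias_params(0, 0, 0), s = 5000, seed = 2)
  expect_equal(nrow(batch), 5000)
  # per-context totals conserved in every replicate
  expect_true(all(batch$e2n_expert + batch$e2n_peer == 30))
  expect_true(all(batch$p2p_expert + batch$p2p_peer == 32))
  se30 <- sqrt(30 * 0.25 / 5000)
  se32 <- sqrt(32 * 0.25 / 5000)
  expect_lt(abs(mean(batch$e2n_expert) - 15), 3 * se30)
  expect_lt(abs(mean(batch$p2p_expert) - 16), 3 * se32)
})

test_that("batch with s = 1 reproduces a single binomial-method run", {
  p <- bias_params(0.25, 0.4, -0.3)
  seeds <- transbias:::derive_cell_seeds(31, 1)
  batch <- simulate_counts_batch(p, s = 1, layout = "eight_cell", seed = 31)
  single <- simulate_experiment(p,
    layout = "eight_cell", seed = seeds[1], method = "binomial"
  )
  expect_equal(
    unname(unlist(batch[1, transbias:::cell_names("eight_cell")])),
    single$count
  )
})

test_that("per-participant and binomial sampling agree in distribution", {
  p <- bias_params(0.3, 0.2, 0)
  design <- experiment_design(30, 32)
  set.seed(8)
  per_part <- vapply(1:3000, function(i) {
    simulate_experiment(p, design, method = "participant")$count[1]
  }, integer(1))
  binom <- simulate_counts_batch(p, design, s = 3000, seed = 8)$e2n_expert
  # two-sample chi-squared on the pooled count histogram
  lv <- 0:30
  tab <- rbind(tabulate(factor(per_part, lv)), tabulate(factor(binom, lv)))
  keep <- colSums(tab) > 5
  ht <- suppressWarnings(stats::chisq.test(tab[, keep]))
  expect_gt(ht$p.value, 1e-4)
  expect_lt(
    abs(mean(per_part) - mean(binom)),
    3 * sqrt(30 * 0.25 / 3000) * sqrt(2)
  )
})

test_that("rare-count frequencies track the closed-form binomial pmf", {
  batch <- simulate_counts_batch(bias_params(0, 0, 0), s = 5000, seed = 13)
  p27 <- dbinom(27, 30, 0.5)
  expect_lt(
    abs(mean(batch$e2n_expert == 27) - p27),
    3 * sqrt(p27 * (1 - p27) / 5000)
  )
  # degenerate parameters: all replicates identical
  degen <- simulate_counts_batch(bias_params(1, 0, 0), s = 50, seed = 1)
  expect_true(all(degen$e2n_expert == 30 & degen$p2p_expert == 32))
})
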