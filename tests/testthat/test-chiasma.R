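test_that("Poisson range probabilities match closed forms", {
  expect_equal(poisson_range_proportion(6.9, 6, 8), 0.428, tolerance = 2e-3)
  expect_equal(poisson_range_proportion(1, 0, 0), exp(-1))
  expect_equal(poisson_range_proportion(3.2, 0, Inf), 1)
  # partition of the support sums to 1
  parts <- c(poisson_range_proportion(5, 0, 3),
             poisson_range_proportion(5, 4, 9),
             poisson_range_proportion(5, 10, Inf))
  expect_equal(sum(parts), 1)
  expect_error(poisson_range_proportion(-1, 0, 2), "positive")
  expect_error(poisson_range_proportion(2, 5, 3), "lo <= hi")
})

test_that("goodness-of-fit bookkeeping is exact in both binned modes", {
  x <- c(rep(4, 6), rep(5, 8), rep(6, 10), rep(7, 12), rep(8, 8), rep(9, 6))
  g <- poisson_gof(x, mode = "paper")
  expect_identical(g$df, 11L)
  expect_equal(sum(g$table$observed), length(x))
  expect_equal(sum(g$table$expected), length(x), tolerance = 1e-6)
  lam <- mean(x)
  exp_paper <- length(x) * c(dpois(0:10, lam), ppois(10, lam,
                                                     lower.tail = FALSE))
  expect_equal(g$chi2,
               sum((c(tabulate(x + 1, 12)[1:12]) - exp_paper)^2 / exp_paper))
  p <- poisson_gof(x, mode = "pooled")
  expect_true(all(p$table$expected >= 5))
  expect_equal(sum(p$table$observed), length(x))
  expect_identical(p$df, nrow(p$table) - 2L)
  expect_error(poisson_gof(rep(0, 10)), "all counts zero")
})

test_that("bootstrap p-values are seeded and consistent with the pooled test", {
  set.seed(61)
  x <- rpois(50, 6.9)
  b1 <- poisson_gof(x, mode = "bootstrap", B = 400, seed = 99)
  b2 <- poisson_gof(x, mode = "bootstrap", B = 400, seed = 99)
  expect_identical(b1$p, b2$p)
  expect_equal(b1$chi2, poisson_gof(x, mode = "pooled")$chi2)
  expect_gt(b1$p, 0.01)
})

test_that("chiasma summaries report exact descriptive statistics", {
  s <- summarize_chiasma(c(7, 7, 7))
  expect_equal(s$mean, 7)
  expect_equal(s$range, c(7, 7))
  expect_equal(s$pct_in_range, 100)
  # 10 cells, 2 univalent pairs in total -> 2 / (5 * 10) = 4%
  fix <- structure(data.frame(cell_id = 1:10,
                              chiasmata = c(5, 6, 7, 7, 8, 6, 7, 9, 6, 7),
                              univalents = c(2, 0, 0, 2, 0, 0, 0, 0, 0, 0),
                              genotype = "x"),
                   class = c("chiasma_sample", "data.frame"))
  expect_equal(summarize_chiasma(fix)$univalent_pct, 4)
  expect_equal(summarize_chiasma(fix, univalent_def = "per_cell")$univalent_pct,
               20)
  expect_error(summarize_chiasma(transform(fix, univalents = c(1, rep(0, 9)))),
               "even")
  # simulated obligate-CO sample has no univalents
  cs <- simulate_chiasma_counts(sim_config(n_cells = 30, seed = 62))
  expect_equal(summarize_chiasma(cs)$univalent_pct, 0)
})

test_that("percent-in-range agrees with the Poisson expectation under the null", {
  set.seed(63)
  x <- rpois(20000, 6.9)
  s <- summarize_chiasma(x)
  expect_lt(abs(s$pct_in_range / 100 - poisson_range_proportion(6.9, 6, 8)),
            4 * sqrt(0.428 * 0.572 / 20000))
})

test_that("rank tests compare count samples and flag degenerate input", {
  expect_warning(rank_test_counts(c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5)),
                 "degenerate")
  expect_equal(suppressWarnings(
    rank_test_counts(c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5)))$p, 1)
  set.seed(64)
  a <- rpois(27, 10); b <- rpois(14, 7)
  rs <- rank_test_counts(a, b)
  expect_match(rs$method, "rank-sum")
  expect_lt(rs$p, 0.05)
  pr <- rank_test_counts(rpois(12, 150), rpois(12, 150), paired = TRUE)
  expect_match(pr$method, "signed-rank")
  expect_gt(pr$p, 0.001)
  expect_error(rank_test_counts(1:3, 1:3), "at least 5")
  expect_error(rank_test_counts(1:6, 1:5, paired = TRUE), "equal-length")
})

test_that("rank-sum test is calibrated under the null and powered for shifts", {
  set.seed(65)
  rej <- mean(replicate(400,
    rank_test_counts(rpois(12, 150), rpois(12, 150))$p < 0.05))
  expect_gt(rej, 0.01); expect_lt(rej, 0.11)
  power <- mean(replicate(300,
    rank_test_counts(rpois(27, 10), rpois(14, 7))$p < 0.05))
  expect_gt(power, 0.7)
})
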