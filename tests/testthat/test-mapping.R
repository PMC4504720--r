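test_that("the Perkins estimator reproduces hand-computed distances", {
  expect_equal(perkins_distance(list(PD = 100, TT = 0, NPD = 0))$cM, 0)
  expect_equal(perkins_distance(list(PD = 0, TT = 100, NPD = 0))$cM, 50)
  d <- perkins_distance(list(PD = 880, TT = 115, NPD = 5))
  expect_equal(d$cM, 7.25)
  expect_equal(d$n, 1000)
  # delta-method SE, written out by hand for these counts
  x <- (115 / 2 + 3 * 5) / 1000
  expect_equal(d$se_cM, 100 * sqrt(((115 / 4 + 9 * 5) / 1000 - x^2) / 1000))
  expect_error(perkins_distance(list(PD = 0, TT = 0, NPD = 0)), "n = 0")
})

test_that("Perkins distance is monotone in TT and NPD at fixed n", {
  base <- perkins_distance(list(PD = 800, TT = 150, NPD = 50))$cM
  expect_gt(perkins_distance(list(PD = 790, TT = 160, NPD = 50))$cM, base)
  expect_gt(perkins_distance(list(PD = 790, TT = 150, NPD = 60))$cM, base)
})

test_that("reported SE matches the sampling spread of the estimator", {
  set.seed(41)
  p <- c(PD = 0.85, TT = 0.14, NPD = 0.01)
  n <- 2000
  est <- replicate(600, {
    cnt <- as.vector(stats::rmultinom(1, n, p))
    perkins_distance(list(PD = cnt[1], TT = cnt[2], NPD = cnt[3]))
  }, simplify = FALSE)
  cms <- vapply(est, `[[`, numeric(1), "cM")
  ses <- vapply(est, `[[`, numeric(1), "se_cM")
  expect_lt(abs(sd(cms) / mean(ses) - 1), 0.15)
})

test_that("map-distance comparison is a calibrated two-sample Z-test", {
  d <- perkins_distance(list(PD = 880, TT = 115, NPD = 5))
  same <- compare_map_distances(d, d)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  set.seed(42)
  p <- c(0.8, 0.19, 0.01)
  rej <- mean(replicate(400, {
    draw <- function() {
      cnt <- as.vector(stats::rmultinom(1, 1500, p))
      perkins_distance(list(PD = cnt[1], TT = cnt[2], NPD = cnt[3]))
    }
    compare_map_distances(draw(), draw())$p < 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("distinct recombination rates are detected with high power", {
  # truths ~27.7 vs ~15.1 cM at n = 1500 per genotype
  set.seed(43)
  p_hi <- c(PD = 1 - 0.50 - 0.018, TT = 0.50, NPD = 0.018)  # ~27.7 cM
  p_lo <- c(PD = 1 - 0.29 - 0.005, TT = 0.29, NPD = 0.005)  # ~16.0 cM
  hits <- mean(replicate(100, {
    a <- as.vector(stats::rmultinom(1, 1500, p_hi))
    b <- as.vector(stats::rmultinom(1, 1500, p_lo))
    compare_map_distances(
      perkins_distance(list(PD = a[1], TT = a[2], NPD = a[3])),
      perkins_distance(list(PD = b[1], TT = b[2], NPD = b[3])))$p < 0.001
  }))
  expect_gt(hits, 0.95)
})

# build a tetrad_tally directly from joint class counts
tally_from_counts <- function(counts) {
  key <- tetrad_class_table()
  key$count <- as.integer(counts[key$label])
  key$count[is.na(key$count)] <- 0L
  joint <- rbind(key, data.frame(label = "OTHER", state1 = NA, state2 = NA,
                                 overlap = NA, count = 0L))
  structure(list(joint = joint, n = sum(joint$count),
                 excluded = data.frame(tetrad_id = character(0),
                                       reason = character(0))),
            class = "tetrad_tally")
}

test_that("interference ratio is 1 when subsets share state proportions", {
  # interval-1 TT fraction 0.2 both among interval-2 PD and interval-2 TT
  tly <- tally_from_counts(c(A = 600, B = 150, C = 200, F = 10, G = 30,
                             H = 10))
  ir <- interference_ratio(tly, 1, 2)
  expect_equal(ir$ir, 1)
  expect_equal(ir$z, 0)
  expect_equal(ir$p, 1)
})

test_that("absent double crossovers drive the interference ratio to zero", {
  tly <- tally_from_counts(c(A = 700, B = 150, C = 150))
  ir <- interference_ratio(tly, 1, 2)
  expect_equal(ir$ir, 0)
  expect_gt(ir$z, 0)
})

test_that("undefined interference ratios raise diagnostic errors", {
  expect_error(interference_ratio(tally_from_counts(c(A = 100))),
               "empty conditioning subset")
  # without-CO subset has zero distance
  expect_error(interference_ratio(tally_from_counts(c(A = 100, C = 50)),
                                  1, 2),
               "IR undefined")
})

test_that("coefficient of coincidence recovers independence and its extremes", {
  tly <- tally_from_counts(c(A = 600, B = 150, C = 200, F = 10, G = 30,
                             H = 10))
  cc <- coefficient_of_coincidence(tly)
  expect_equal(cc$f1, 0.2)
  expect_equal(cc$f2, 0.25)
  expect_equal(cc$expected_dco, 0.05)
  expect_equal(cc$coc, 1)
  # no double COs at all
  expect_equal(coefficient_of_coincidence(
    tally_from_counts(c(A = 700, B = 150, C = 150)))$coc, 0)
  # gamete-level definition on a hand-checkable table
  tly2 <- tally_from_counts(c(A = 560, B = 140, C = 225, F = 15, G = 30,
                              H = 30))
  cg <- coefficient_of_coincidence(tly2, definition = "gamete")
  n <- 1000
  f1 <- ((140 + 15 + 30 + 30) / 2) / n
  f2 <- ((225 + 15 + 30 + 30) / 2) / n
  obs <- (15 * 2 + 30 * 1 + 30 * 0) / (4 * n)
  expect_equal(cg$f1, f1)
  expect_equal(cg$f2, f2)
  expect_equal(cg$observed_dco, obs)
  expect_equal(cg$coc, obs / (f1 * f2))
})

test_that("interference ratio falls with interference strength in simulation", {
  mk <- c(0, 10, 20)
  run <- function(shape, seed) {
    tt <- simulate_ftl_tetrads(sim_config(marker_positions_cM = mk,
                                          interference_shape = shape,
                                          n_tetrads = 6000, seed = seed))
    tly <- tally_tetrads(tt)
    c(interference_ratio(tly)$ir, coefficient_of_coincidence(tly)$coc)
  }
  nul <- run(1, 51)
  strong <- run(5, 52)
  expect_gt(nul[1], 0.8); expect_lt(nul[1], 1.2)
  expect_gt(nul[2], 0.8); expect_lt(nul[2], 1.2)
  expect_lt(strong[1], nul[1])
  expect_lt(strong[2], nul[2])
})
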