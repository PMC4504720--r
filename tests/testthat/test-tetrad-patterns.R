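test_that("a crossover-free bivalent yields a parental ditype tetrad", {
  ev <- data.frame(position = numeric(0), pairing = integer(0),
                   pathway = character(0))
  tet <- events_to_tetrad(ev, c(0, 0.1, 0.2), length_m = 0.2)
  expect_identical(rowSums(tet), c(3, 3, 0, 0))
  expect_identical(classify_tetrad(tet)$label, "A")
})

test_that("tetrad patterns match the brute-force chiasma-diagram oracle", {
  # exhaustive: none / single CO per interval / one CO in each interval,
  # over all chromatid pairings
  for (p1 in c(list(NULL), as.list(1:4))) {
    for (p2 in c(list(NULL), as.list(1:4))) {
      tet <- events_to_tetrad(impl_events(p1, p2), c(0, 0.1, 0.2),
                              length_m = 0.2)
      expect_identical(unname(tet), unname(oracle_tetrad(p1, p2)),
                       info = sprintf("p1=%s p2=%s",
                                      deparse(p1), deparse(p2)))
      # balanced segregation: every marker present in exactly 2 of 4 grains
      expect_identical(unname(colSums(tet)), c(2, 2, 2))
    }
  }
})

test_that("single crossovers recombine only their own interval", {
  for (p1 in 1:4) {
    tet <- events_to_tetrad(impl_events(p1 = p1), c(0, 0.1, 0.2))
    s1 <- interval_state(tet, 1, 2)
    s2 <- interval_state(tet, 2, 3)
    expect_identical(s1$state, "TT")
    expect_length(s1$recombinant_grains, 2L)
    expect_identical(s2$state, "PD")
    expect_identical(classify_tetrad(tet)$label, "B")
  }
})

test_that("double crossovers give the classical strand relationships", {
  # two-strand (same pairing): both intervals TT, same two grains recombinant
  tet2 <- events_to_tetrad(impl_events(1, 1), c(0, 0.1, 0.2))
  cls2 <- classify_tetrad(tet2)
  expect_identical(cls2[c("state1", "state2")],
                   list(state1 = "TT", state2 = "TT"))
  expect_identical(cls2$overlap, 2L)
  expect_identical(cls2$label, "F")
  # four-strand (disjoint pairings): every grain recombinant in one interval
  tet4 <- events_to_tetrad(impl_events(1, 4), c(0, 0.1, 0.2))
  cls4 <- classify_tetrad(tet4)
  expect_identical(cls4$overlap, 0L)
  r1 <- interval_state(tet4, 1, 2)$recombinant_grains
  r2 <- interval_state(tet4, 2, 3)$recombinant_grains
  expect_identical(sort(c(r1, r2)), 1:4)
  # overlap subtype frequencies over all 16 pairings: 4 two-strand,
  # 8 three-strand, 4 four-strand
  ov <- vapply(1:4, function(p1) vapply(1:4, function(p2)
    classify_tetrad(events_to_tetrad(impl_events(p1, p2),
                                     c(0, 0.1, 0.2)))$overlap,
    integer(1)), integer(4))
  expect_identical(as.vector(table(ov)), c(4L, 8L, 4L))
})

test_that("classification is invariant under grain permutation", {
  set.seed(21)
  tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 30, seed = 21))
  mk <- c("c1", "c2", "c3")
  for (id in unique(tt$tetrad_id)[1:10]) {
    tet <- as.matrix(tt[tt$tetrad_id == id, mk])
    ref <- classify_tetrad(tet)
    perm <- sample(4)
    got <- classify_tetrad(tet[perm, ])
    expect_identical(got[c("state1", "state2", "overlap", "label")],
                     ref[c("state1", "state2", "overlap", "label")])
  }
})

test_that("interval scoring maps recombinant-grain counts to PD/TT/NPD", {
  expect_identical(
    interval_state(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)), 1, 2)$state,
    "PD")
  expect_identical(
    interval_state(rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0)), 1, 2)$state,
    "TT")
  expect_identical(
    interval_state(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)), 1, 2)$state,
    "NPD")
  expect_error(
    interval_state(rbind(c(1, 0), c(1, 1), c(0, 0), c(0, 0)), 1, 2),
    class = "ambiguous_tetrad")
})

test_that("marker outside the bivalent is rejected", {
  ev <- data.frame(position = 0.05, pairing = 1L, pathway = "interfering")
  expect_error(events_to_tetrad(ev, c(0, 0.1, 0.3), length_m = 0.2),
               "outside")
})
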