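#' Perkins map distance from tetrad counts
#'
#' The tetrad estimator of genetic map distance,
#' \deqn{\hat X = 100 (TT/2 + 3\,NPD)/n \ \mathrm{cM},}
#' which corrects for the double crossovers revealed by non-parental
#' ditypes. The standard error comes from the multinomial delta method: with
#' per-tetrad contribution \eqn{w \in \{0, 1/2, 3\}},
#' \eqn{SE = 100\sqrt{(\overline{w^2} - \bar w^2)/n}}.
#'
#' @param counts An `interval_counts` object, or any list/vector with
#'   components `PD`, `TT`, `NPD`.
#' @return Object of class `map_distance`: list with `cM`, `se_cM`, `n`,
#'   and the input `counts`.
#' @examples
#' perkins_distance(list(PD = 880, TT = 115, NPD = 5))  # 7.25 cM
#' @export
perkins_distance <- function(counts) {
  pd <- counts[["PD"]]; tt <- counts[["TT"]]; npd <- counts[["NPD"]]
  if (any(c(pd, tt, npd) < 0) || any(c(pd, tt, npd) %% 1 != 0))
    stop("PD/TT/NPD must be non-negative integers", call. = FALSE)
  n <- pd + tt + npd
  if (n == 0) stop("no classified tetrads (n = 0)", call. = FALSE)
  x <- (tt / 2 + 3 * npd) / n
  v <- (tt / 4 + 9 * npd) / n - x^2
  structure(list(cM = 100 * x,
                 se_cM = 100 * sqrt(max(v, 0) / n),
                 n = n,
                 counts = list(PD = pd, TT = tt, NPD = npd)),
            class = "map_distance")
}

#' @export
print.map_distance <- function(x, ...) {
  cat(sprintf("%.1f cM (SE %.2f, n = %d; PD %d / TT %d / NPD %d)\n",
              x$cM, x$se_cM, x$n,
              x$counts$PD, x$counts$TT, x$counts$NPD))
  invisible(x)
}

#' Compare two map distances by a two-sample Z-test
#'
#' @param a,b `map_distance` objects.
#' @return List with `z` and two-sided `p`.
#' @examples
#' d1 <- perkins_distance(list(PD = 880, TT = 115, NPD = 5))
#' d2 <- perkins_distance(list(PD = 850, TT = 145, NPD = 5))
#' compare_map_distances(d1, d2)
#' @export
compare_map_distances <- function(a, b) {
  stopifnot(inherits(a, "map_distance"), inherits(b, "map_distance"))
  pooled <- sqrt(a$se_cM^2 + b$se_cM^2)
  if (!is.finite(pooled) || pooled == 0)
    stop("pooled standard error is zero; cannot compare", call. = FALSE)
  z <- (a$cM - b$cM) / pooled
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Interval counts of the test interval among tetrads in a subset of the
# conditioning interval's states.
subset_counts <- function(tally, test, conditioning, cond_states) {
  j <- tally$joint
  keep <- !is.na(j$state1) & j[[paste0("state", conditioning)]] %in% cond_states
  st <- j[[paste0("state", test)]][keep]
  cnt <- j$count[keep]
  out <- list(PD = sum(cnt[st == "PD"]), TT = sum(cnt[st == "TT"]),
              NPD = sum(cnt[st == "NPD"]))
  out$n <- out$PD + out$TT + out$NPD
  structure(out, class = "interval_counts")
}

#' Interference ratio between adjacent intervals
#'
#' The genetic estimate of crossover interference of Malkova and colleagues:
#' the Perkins map distance of the test interval among tetrads that carry a
#' crossover in the adjacent (conditioning) interval — i.e. are TT or NPD
#' there — divided by the distance among tetrads that are PD there. The
#' ratio is 1 when crossovers in the two intervals are independent, falls
#' toward 0 with increasing positive interference, and exceeds 1 under
#' negative interference. The accompanying Z statistic tests
#' \eqn{d_{with} = d_{without}} by the delta method on the two subset
#' estimates.
#'
#' @param tally A [tally_tetrads()] result.
#' @param test_interval Interval whose map distance is conditioned (1 or 2).
#' @param conditioning_interval Adjacent interval supplying the
#'   with/without-crossover split.
#' @return Object of class `interference_result`: list with `ir`,
#'   `d_with`, `d_without` (both `map_distance`), `z`, `p`.
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 4000, seed = 1))
#' interference_ratio(tally_tetrads(tt))
#' @export
interference_ratio <- function(tally, test_interval = 1L,
                               conditioning_interval = 2L) {
  stopifnot(inherits(tally, "tetrad_tally"))
  if (test_interval == conditioning_interval)
    stop("test and conditioning intervals must differ", call. = FALSE)
  with_cnt <- subset_counts(tally, test_interval, conditioning_interval,
                            c("TT", "NPD"))
  without_cnt <- subset_counts(tally, test_interval, conditioning_interval,
                               "PD")
  if (with_cnt$n == 0 || without_cnt$n == 0)
    stop(sprintf(
      "empty conditioning subset (with-CO n = %d, without-CO n = %d)",
      with_cnt$n, without_cnt$n), call. = FALSE)
  d_with <- perkins_distance(with_cnt)
  d_without <- perkins_distance(without_cnt)
  if (d_without$cM == 0)
    stop("map distance without adjacent CO is zero; IR undefined (PD ",
         without_cnt$PD, ", TT ", without_cnt$TT, ", NPD ", without_cnt$NPD,
         ")", call. = FALSE)
  se <- sqrt(d_with$se_cM^2 + d_without$se_cM^2)
  z <- if (se > 0) (d_without$cM - d_with$cM) / se else 0
  structure(list(ir = d_with$cM / d_without$cM,
                 d_with = d_with, d_without = d_without,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf(
    "Interference ratio %.3f (with CO %.1f cM, n=%d; without %.1f cM, n=%d)\n",
    x$ir, x$d_with$cM, x$d_with$n, x$d_without$cM, x$d_without$n))
  cat(sprintf("  Z = %.2f, two-sided P = %.3g\n", x$z, x$p))
  invisible(x)
}

#' Coefficient of coincidence for two adjacent intervals
#'
#' Observed frequency of double crossovers in the two intervals divided by
#' the frequency expected if the intervals were independent (the product of
#' the single-interval crossover frequencies). CoC is 1 in the absence of
#' interference and 0 when interference is complete.
#'
#' Two definitions are available. `"tetrad"` (default) works at the tetrad
#' level: an interval "has a CO" in a tetrad if its state is TT or NPD, and
#' the observed double-CO frequency is the fraction of tetrads non-PD in
#' both. `"gamete"` works at the gamete level: the interval frequency is
#' the recombinant-gamete fraction `(TT/2 + NPD)/n` and the observed
#' double-CO frequency is the fraction of grains recombinant in both
#' intervals (computable from the joint classes and TT/TT overlaps).
#'
#' @param tally A [tally_tetrads()] result.
#' @param definition `"tetrad"` or `"gamete"`.
#' @return Object of class `coc_result`: list with `f1`, `f2`,
#'   `observed_dco`, `expected_dco`, `coc`, `definition`, `n`.
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 4000, seed = 1))
#' coefficient_of_coincidence(tally_tetrads(tt))
#' @export
coefficient_of_coincidence <- function(tally,
                                       definition = c("tetrad", "gamete")) {
  stopifnot(inherits(tally, "tetrad_tally"))
  definition <- match.arg(definition)
  j <- tally$joint[!is.na(tally$joint$state1), ]
  n <- sum(j$count)
  c1 <- interval_counts(tally, 1L)
  c2 <- interval_counts(tally, 2L)
  if (definition == "tetrad") {
    f1 <- (c1$TT + c1$NPD) / n
    f2 <- (c2$TT + c2$NPD) / n
    obs <- sum(j$count[j$state1 != "PD" & j$state2 != "PD"]) / n
  } else {
    f1 <- (c1$TT / 2 + c1$NPD) / n
    f2 <- (c2$TT / 2 + c2$NPD) / n
    # grains recombinant in both intervals, per joint class
    both <- ifelse(j$state1 == "TT" & j$state2 == "TT", j$overlap,
            ifelse(j$state1 == "NPD" & j$state2 == "NPD", 4L,
            ifelse((j$state1 == "NPD" & j$state2 == "TT") |
                   (j$state1 == "TT" & j$state2 == "NPD"), 2L, 0L)))
    obs <- sum(j$count * both) / (4 * n)
  }
  if (f1 == 0 || f2 == 0)
    stop("a marginal crossover frequency is zero; CoC undefined",
         call. = FALSE)
  expected <- f1 * f2
  structure(list(f1 = f1, f2 = f2, observed_dco = obs,
                 expected_dco = expected, coc = obs / expected,
                 definition = definition, n = n),
            class = "coc_result")
}

#' @export
print.coc_result <- function(x, ...) {
  cat(sprintf(
    "CoC = %.3f (%s definition; f1 %.4f, f2 %.4f, observed DCO %.4f, expected %.4f, n = %d)\n",
    x$coc, x$definition, x$f1, x$f2, x$observed_dco, x$expected_dco, x$n))
  invisible(x)
}
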