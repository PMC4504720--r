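as_count_vector <- function(sample) {
  x <- if (is.data.frame(sample)) sample$chiasmata else sample
  if (is.null(x) || !is.numeric(x))
    stop("need a numeric count vector or a data frame with `chiasmata`",
         call. = FALSE)
  if (any(x < 0) || any(x %% 1 != 0))
    stop("counts must be non-negative integers", call. = FALSE)
  as.integer(x)
}

#' Poisson probability of a count range
#'
#' Probability that a Poisson variable with the given mean falls in
#' `[lo, hi]` (inclusive); with `hi = Inf` the upper tail is included. Used
#' to compare an observed percent-of-cells-in-range against the random
#' (no-crossover-control) expectation.
#'
#' @param mean Poisson mean (> 0).
#' @param lo,hi Integer bounds, `0 <= lo <= hi`.
#' @return A probability.
#' @examples
#' poisson_range_proportion(6.9, 6, 8)  # 0.428
#' @export
poisson_range_proportion <- function(mean, lo, hi) {
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (lo < 0 || hi < lo) stop("need 0 <= lo <= hi", call. = FALSE)
  upper <- if (is.infinite(hi)) 1 else stats::ppois(hi, mean)
  lower <- if (lo == 0) 0 else stats::ppois(lo - 1, mean)
  upper - lower
}

# Pool adjacent Poisson bins (0..tail) until each expected count is >= 5.
# Returns breaks as a list of integer bin memberships plus expected probs.
pooled_bins <- function(lambda, n, min_expected = 5) {
  top <- max(stats::qpois(1 - 1e-9, lambda), 1L)
  probs <- c(stats::dpois(0:(top - 1L), lambda),
             stats::ppois(top - 1L, lambda, lower.tail = FALSE))
  support <- 0:top  # last entry means ">= top"
  groups <- integer(length(probs))
  gid <- 1L; acc <- 0
  for (i in seq_along(probs)) {
    groups[i] <- gid
    acc <- acc + n * probs[i]
    if (acc >= min_expected && i < length(probs)) { gid <- gid + 1L; acc <- 0 }
  }
  # fold a deficient final bin into its neighbour
  last <- groups == max(groups)
  if (sum(n * probs[last]) < min_expected && max(groups) > 1L)
    groups[last] <- max(groups) - 1L
  list(support = support, groups = groups, probs = probs)
}

gof_table <- function(x, lambda, support, groups, probs) {
  n <- length(x)
  xc <- pmin(x, max(support))
  obs_raw <- tabulate(xc + 1L, nbins = length(support))
  obs <- as.vector(rowsum(obs_raw, groups))
  expd <- as.vector(rowsum(length(x) * probs, groups))
  data.frame(bin = vapply(split(support, groups), function(s)
    if (length(s) == 1L) as.character(s)
    else paste0(s[1L], "-", s[length(s)]), character(1)),
    observed = obs, expected = expd)
}

#' Poisson goodness-of-fit for chiasma counts
#'
#' Chi-squared comparison of observed per-cell chiasma counts with the
#' Poisson distribution of the same mean. Without crossover control,
#' chiasma counts are expected to be Poisson; interference concentrates
#' counts around the mean and produces lack of fit.
#'
#' Three modes:
#' \describe{
#'   \item{`"pooled"` (default)}{Adjacent count categories are merged until
#'     every expected count is at least 5, and one degree of freedom is
#'     subtracted for the estimated mean (`df = k - 2`). The statistically
#'     conventional choice.}
#'   \item{`"paper"`}{Twelve fixed categories (counts 0-10 and a 11-or-more
#'     tail) with `df = 11`, i.e. no correction for the estimated mean —
#'     provided for comparability with published chi-squared values quoted
#'     with 11 degrees of freedom.}
#'   \item{`"bootstrap"`}{Parametric bootstrap: the pooled statistic is
#'     recomputed on `B` Poisson resamples (mean re-estimated each time)
#'     and the p-value is the fraction at least as extreme.}
#' }
#'
#' @param sample A `chiasma_sample` data frame or a bare count vector.
#' @param mode `"pooled"`, `"paper"`, or `"bootstrap"`.
#' @param B Bootstrap replicates (bootstrap mode).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `gof_result`: list with `chi2`, `df` (NA for
#'   bootstrap), `p`, `mode`, `mean`, `n`, and `table` (observed/expected
#'   per bin).
#' @examples
#' cs <- simulate_chiasma_counts(sim_config(n_cells = 50, seed = 1))
#' poisson_gof(cs)
#' @export
poisson_gof <- function(sample, mode = c("pooled", "paper", "bootstrap"),
                        B = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  x <- as_count_vector(sample)
  n <- length(x)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  lambda <- mean(x)
  if (lambda == 0) stop("degenerate sample: all counts zero", call. = FALSE)
  chi2_of <- function(x, lambda, bins) {
    tab <- gof_table(x, lambda, bins$support, bins$groups, bins$probs)
    sum((tab$observed - tab$expected)^2 / tab$expected)
  }
  if (mode == "paper") {
    support <- 0:11
    probs <- c(stats::dpois(0:10, lambda),
               stats::ppois(10, lambda, lower.tail = FALSE))
    bins <- list(support = support, groups = seq_along(probs), probs = probs)
    tab <- gof_table(x, lambda, bins$support, bins$groups, bins$probs)
    chi2 <- sum((tab$observed - tab$expected)^2 / tab$expected)
    df <- 11L
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    bins <- pooled_bins(lambda, n)
    tab <- gof_table(x, lambda, bins$support, bins$groups, bins$probs)
    chi2 <- sum((tab$observed - tab$expected)^2 / tab$expected)
    k <- max(bins$groups)
    df <- k - 2L
    if (mode == "pooled") {
      if (df < 1L)
        stop("too few count categories for a pooled chi-squared test",
             call. = FALSE)
      p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    } else {
      if (!is.null(seed)) set.seed(seed)
      boot <- numeric(B)
      for (b in seq_len(B)) {
        y <- stats::rpois(n, lambda)
        lb <- mean(y)
        if (lb == 0) { boot[b] <- 0; next }
        boot[b] <- chi2_of(y, lb, pooled_bins(lb, n))
      }
      p <- (1 + sum(boot >= chi2)) / (B + 1)
      df <- NA_integer_
    }
  }
  structure(list(chi2 = chi2, df = df, p = p, mode = mode,
                 mean = lambda, n = n, table = tab),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Poisson goodness of fit (%s mode): chi2 = %.2f, %s, P = %.3g\n",
              x$mode, x$chi2,
              if (is.na(x$df)) "bootstrap" else paste0("df = ", x$df), x$p))
  cat(sprintf("  mean = %.2f over %d cells\n", x$mean, x$n))
  invisible(x)
}

#' Descriptive summary of a chiasma sample
#'
#' Mean and range of per-cell chiasma counts, the percentage of cells in a
#' count window around the mean (over-representation relative to
#' [poisson_range_proportion()] indicates crossover control), and the
#' univalent frequency.
#'
#' @param sample A `chiasma_sample` data frame (or count vector; then no
#'   univalent frequency is computed).
#' @param range_lo,range_hi Count window, default 6-8.
#' @param univalent_def `"per_bivalent"`: univalent pairs per bivalent
#'   opportunity, `100 * (sum(univalents)/2) / (5 * n_cells)`;
#'   `"per_cell"`: percent of cells with any univalent.
#' @return Object of class `chiasma_summary`: list with `mean`, `range`,
#'   `pct_in_range`, `range_window`, `univalent_pct` (NA if unavailable),
#'   `univalent_def`, `n`.
#' @examples
#' cs <- simulate_chiasma_counts(sim_config(n_cells = 50, seed = 1))
#' summarize_chiasma(cs)
#' @export
summarize_chiasma <- function(sample, range_lo = 6L, range_hi = 8L,
                              univalent_def = c("per_bivalent", "per_cell")) {
  univalent_def <- match.arg(univalent_def)
  x <- as_count_vector(sample)
  if (!length(x)) stop("empty sample", call. = FALSE)
  uni <- if (is.data.frame(sample)) sample$univalents else NULL
  upct <- NA_real_
  if (!is.null(uni)) {
    if (any(uni %% 2 != 0))
      stop("univalent counts must be even (univalents come in pairs)",
           call. = FALSE)
    upct <- if (univalent_def == "per_bivalent")
      100 * (sum(uni) / 2) / (5 * length(x))
    else 100 * mean(uni > 0)
  }
  structure(list(mean = mean(x), range = range(x),
                 pct_in_range = 100 * mean(x >= range_lo & x <= range_hi),
                 range_window = c(range_lo, range_hi),
                 univalent_pct = upct, univalent_def = univalent_def,
                 n = length(x)),
            class = "chiasma_summary")
}

#' @export
print.chiasma_summary <- function(x, ...) {
  cat(sprintf("%d cells: mean %.1f chiasmata, range %d-%d; %.1f%% in [%d, %d]\n",
              x$n, x$mean, x$range[1], x$range[2], x$pct_in_range,
              x$range_window[1], x$range_window[2]))
  if (!is.na(x$univalent_pct))
    cat(sprintf("  univalent frequency %.1f%% (%s)\n", x$univalent_pct,
                x$univalent_def))
  invisible(x)
}

#' Rank-based comparison of two count samples
#'
#' Compares focus or chiasma counts between genotypes with a Wilcoxon rank
#' test: the unpaired rank-sum (Mann-Whitney) test by default, or the
#' paired signed-rank test with `paired = TRUE`. Ties are handled by the
#' normal approximation.
#'
#' @param a,b Numeric count vectors (equal length when `paired = TRUE`).
#' @param paired Use the signed-rank test on pairwise differences.
#' @return List with `statistic`, `p`, and `method`.
#' @examples
#' rank_test_counts(rpois(20, 10), rpois(20, 7))
#' @export
rank_test_counts <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal-length samples", call. = FALSE)
  if (!paired && (length(a) < 5L || length(b) < 5L))
    stop("need at least 5 observations per group", call. = FALSE)
  method <- if (paired) "Wilcoxon signed-rank (paired)"
            else "Wilcoxon rank-sum (unpaired)"
  degenerate <- if (paired) all(a == b)
                else length(unique(c(a, b))) == 1L
  if (degenerate) {
    warning("degenerate all-tied input; returning p = 1")
    return(list(statistic = NA_real_, p = 1, method = method))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  list(statistic = unname(wt$statistic), p = wt$p.value, method = method)
}
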