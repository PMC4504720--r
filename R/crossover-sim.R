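#' Simulate crossover positions under a stationary gamma renewal model
#'
#' Draws one realisation of crossover positions along a bivalent of given
#' genetic length. Inter-event distances are gamma distributed with shape
#' `shape` and mean `1/(2 * rate_scale)` Morgans, so the process places on
#' average `2 * rate_scale` events per Morgan on the four-chromatid bundle
#' (the classical two-events-per-Morgan bivalent rate when
#' `rate_scale = 1`). `shape = 1` gives a homogeneous Poisson process (no
#' interference); larger shapes space events more evenly (positive
#' interference).
#'
#' The process is stationary: the first event is drawn from the equilibrium
#' forward-recurrence distribution (a uniform fraction of a length-biased
#' inter-event gap), not anchored at the left end, so event-count
#' distributions do not depend on where the observation window sits.
#'
#' @param length_m Bivalent length in Morgans (> 0).
#' @param shape Gamma shape parameter \eqn{\nu > 0}; 1 = no interference.
#' @param rate_scale Multiplier on the base rate of 2 events per Morgan.
#' @return Numeric vector of event positions in Morgans, sorted increasing
#'   (possibly empty).
#' @seealso [assign_chromatids()], [events_to_tetrad()]
#' @examples
#' set.seed(1)
#' simulate_crossovers(1.0, shape = 5)
#' @export
simulate_crossovers <- function(length_m, shape, rate_scale = 1) {
  if (!is.numeric(length_m) || length(length_m) != 1L || length_m <= 0)
    stop("`length_m` must be a single positive number", call. = FALSE)
  if (!is.numeric(shape) || length(shape) != 1L || shape <= 0)
    stop("`shape` must be a single positive number", call. = FALSE)
  if (!is.numeric(rate_scale) || length(rate_scale) != 1L || rate_scale <= 0)
    stop("`rate_scale` must be a single positive number", call. = FALSE)
  pos <- renewal_positions(1L, length_m, shape, 2 * rate_scale)[[1L]]
  pos
}

# Vectorised renewal engine: n independent realisations on [0, length_m].
# Inter-event gaps ~ Gamma(shape, rate = shape * rate) so the mean gap is
# 1/rate; the first event is U * Gamma(shape + 1, shape * rate), the exact
# forward-recurrence draw for a stationary renewal process (length-biased
# gap times a uniform fraction).  Returns a list of n position vectors.
renewal_positions <- function(n, length_m, shape, rate) {
  if (rate <= 0) return(rep(list(numeric(0)), n))
  brate <- shape * rate
  cum <- stats::runif(n) * stats::rgamma(n, shape = shape + 1, rate = brate)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- numeric(0)
  alive <- which(cum <= length_m)
  while (length(alive)) {
    for (i in alive) out[[i]] <- c(out[[i]], cum[i])
    cum[alive] <- cum[alive] + stats::rgamma(length(alive), shape = shape,
                                             rate = brate)
    alive <- alive[cum[alive] <= length_m]
  }
  out
}

# Same engine returning only event counts (for chiasma simulation).
renewal_counts <- function(n, length_m, shape, rate) {
  if (rate <= 0) return(integer(n))
  brate <- shape * rate
  cum <- stats::runif(n) * stats::rgamma(n, shape = shape + 1, rate = brate)
  counts <- integer(n)
  alive <- which(cum <= length_m)
  while (length(alive)) {
    counts[alive] <- counts[alive] + 1L
    cum[alive] <- cum[alive] + stats::rgamma(length(alive), shape = shape,
                                             rate = brate)
    alive <- alive[cum[alive] <= length_m]
  }
  counts
}

# The four non-sister chromatid pairings.  Chromatids 1,2 are the sisters of
# homolog 1 (the fluorophore-carrying parent when markers are in coupling);
# 3,4 are the sisters of homolog 2.
chromatid_pairings <- function() {
  list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
}

#' Assign crossover events to chromatid pairs
#'
#' Each crossover on the bivalent involves one chromatid from each homolog.
#' Under no chromatid interference every event independently picks one of
#' the four non-sister pairings with probability 1/4.
#'
#' @param events Data frame of events with a `position` column (Morgans), or
#'   a bare numeric vector of positions.
#' @param pathway Optional character vector recycled across events
#'   (`"interfering"` or `"non-interfering"`); recorded, not used.
#' @return Data frame with columns `position`, `pairing` (1-4, indexing
#'   [chromatid_pairings()]), and `pathway`.
#' @examples
#' set.seed(1)
#' assign_chromatids(c(0.1, 0.4))
#' @export
assign_chromatids <- function(events, pathway = "interfering") {
  if (is.numeric(events)) events <- data.frame(position = events)
  n <- nrow(events)
  data.frame(
    position = events$position,
    pairing = if (n) sample.int(4L, n, replace = TRUE) else integer(0),
    pathway = rep_len(if (n) pathway else character(0), n),
    stringsAsFactors = FALSE
  )
}

#' Convert crossover events on a bivalent into a pollen tetrad
#'
#' Markers are hemizygous transgenes in coupling: chromatids 1 and 2 are the
#' sisters of the fluorophore-carrying homolog, 3 and 4 of the untagged
#' homolog. Each meiotic product is traced through the chiasma diagram: a
#' gamete starts on one chromatid and, at every crossover whose chromatid
#' pair includes the line it is currently travelling on, switches to the
#' partner line. A grain carries a fluorophore iff the line it occupies at
#' that marker belongs to the tagged homolog. Because every crossover swaps
#' the occupancy of exactly two lines, each marker is always carried by
#' exactly two of the four grains (balanced segregation). The four traced
#' products become the four pollen grains of a `qrt`-style tetrad.
#'
#' @param events Data frame as returned by [assign_chromatids()].
#' @param marker_positions_m Numeric vector of marker positions in Morgans,
#'   strictly increasing, within `[0, length_m]`.
#' @param length_m Bivalent length in Morgans (markers must lie inside).
#' @return Integer matrix with 4 rows (grains) and one 0/1 column per marker.
#' @examples
#' ev <- data.frame(position = 0.05, pairing = 1L, pathway = "interfering")
#' events_to_tetrad(ev, marker_positions_m = c(0, 0.1, 0.2), length_m = 0.2)
#' @export
events_to_tetrad <- function(events, marker_positions_m, length_m = NULL) {
  m <- marker_positions_m
  if (is.unsorted(m, strictly = TRUE))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (!is.null(length_m) && (any(m < 0) || any(m > length_m)))
    stop("marker outside bivalent", call. = FALSE)
  pairs <- chromatid_pairings()
  o <- order(events$position)
  pos <- events$position[o]
  pairing <- events$pairing[o]
  tet <- matrix(0L, nrow = 4L, ncol = length(m))
  for (start in 1:4) {
    cur <- start
    k <- 1L
    for (j in seq_along(m)) {
      while (k <= length(pos) && pos[k] < m[j]) {
        p <- pairs[[pairing[k]]]
        if (cur == p[1L]) cur <- p[2L] else if (cur == p[2L]) cur <- p[1L]
        k <- k + 1L
      }
      tet[start, j] <- as.integer(cur <= 2L)
    }
  }
  colnames(tet) <- paste0("c", seq_along(m))
  tet
}
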