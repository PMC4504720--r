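#' Configuration for the meiosis simulator
#'
#' Bundles and validates the parameters of the synthetic meiosis generator.
#' Crossovers arise from two superposed pathways: an interference-sensitive
#' (Class I) gamma-renewal process carrying fraction `1 - class2_fraction` of
#' the total rate, and an interference-insensitive (Class II) homogeneous
#' Poisson process carrying the rest. The default Class II fraction of 0.15
#' reflects the roughly 85% of Arabidopsis crossovers that show interference.
#' The total rate is always 2 events per Morgan on the bivalent, so genetic
#' map length is preserved regardless of the mixture.
#'
#' @param marker_positions_cM Ordered genetic positions (cM) of 2-3 FTL
#'   markers on one linkage group. The default mirrors a wild-type pair of
#'   adjacent intervals of 6.1 and 5.5 cM.
#' @param interference_shape Gamma shape \eqn{\nu > 0} of the Class I
#'   pathway; 1 = no interference (Poisson).
#' @param class2_fraction Fraction of crossovers from the non-interfering
#'   pathway, in `[0, 1)`.
#' @param obligate_co Force at least one crossover per bivalent by rejection
#'   sampling. Off by default for tetrad simulation; [simulate_chiasma_counts()]
#'   turns it on by default (every metaphase-I bivalent needs a chiasma to
#'   stay paired).
#' @param n_tetrads Number of tetrads for [simulate_ftl_tetrads()].
#' @param n_cells Number of cells for [simulate_chiasma_counts()].
#' @param bivalent_lengths_cM Genetic lengths (cM) of the five bivalents for
#'   whole-genome chiasma simulation. The default sums to 345 cM so the
#'   expected chiasma count without an obligate crossover is 6.9 per cell.
#' @param viability_filter Drop tetrads containing grains flagged unbalanced
#'   (FTL scoring only sees viable tetrads).
#' @param marker_names Column names for the fluorophore calls.
#' @param genotype Label attached to simulated chiasma samples.
#' @param seed Integer seed; every generator call with the same config and
#'   seed reproduces the same dataset.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(n_tetrads = 100, seed = 1)
#' @export
sim_config <- function(marker_positions_cM = c(0, 6.1, 11.6),
                       interference_shape = 1,
                       class2_fraction = 0.15,
                       obligate_co = FALSE,
                       n_tetrads = 1000L,
                       n_cells = 50L,
                       bivalent_lengths_cM = c(95, 75, 60, 60, 55),
                       viability_filter = FALSE,
                       marker_names = NULL,
                       genotype = "sim",
                       seed = NULL) {
  if (length(marker_positions_cM) < 2L || length(marker_positions_cM) > 3L)
    stop("need 2 or 3 marker positions", call. = FALSE)
  if (is.unsorted(marker_positions_cM, strictly = TRUE))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (interference_shape <= 0)
    stop("`interference_shape` must be positive", call. = FALSE)
  if (class2_fraction < 0 || class2_fraction >= 1)
    stop("`class2_fraction` must be in [0, 1)", call. = FALSE)
  if (n_tetrads < 1) stop("`n_tetrads` must be positive", call. = FALSE)
  if (n_cells < 1) stop("`n_cells` must be positive", call. = FALSE)
  if (any(bivalent_lengths_cM <= 0))
    stop("bivalent lengths must be positive", call. = FALSE)
  if (is.null(marker_names))
    marker_names <- paste0("c", seq_along(marker_positions_cM))
  structure(list(
    marker_positions_cM = marker_positions_cM,
    interference_shape = interference_shape,
    class2_fraction = class2_fraction,
    obligate_co = isTRUE(obligate_co),
    n_tetrads = as.integer(n_tetrads),
    n_cells = as.integer(n_cells),
    bivalent_lengths_cM = bivalent_lengths_cM,
    viability_filter = isTRUE(viability_filter),
    marker_names = marker_names,
    genotype = genotype,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Meiosis simulator configuration\n")
  cat("  markers (cM):       ", paste(x$marker_positions_cM, collapse = ", "),
      "\n")
  cat("  interference shape: ", x$interference_shape, "\n")
  cat("  Class II fraction:  ", x$class2_fraction, "\n")
  cat("  obligate CO:        ", x$obligate_co, "\n")
  cat("  n tetrads / cells:  ", x$n_tetrads, "/", x$n_cells, "\n")
  cat("  bivalents (cM):     ", paste(x$bivalent_lengths_cM, collapse = ", "),
      "\n")
  cat("  seed:               ",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  invisible(x)
}

# Draw crossover events for n bivalents of span length_m under the two-pathway
# model; returns a list of data.frames (position, pairing, pathway).
draw_bivalent_events <- function(n, length_m, shape, class2) {
  interf <- renewal_positions(n, length_m, shape, 2 * (1 - class2))
  n2 <- if (class2 > 0) stats::rpois(n, 2 * class2 * length_m) else integer(n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- interf[[i]]
    p2 <- if (n2[i]) stats::runif(n2[i], 0, length_m) else numeric(0)
    pos <- c(p1, p2)
    path <- rep(c("interfering", "non-interfering"),
                c(length(p1), length(p2)))
    o <- order(pos)
    out[[i]] <- list(
      position = pos[o],
      pairing = if (length(pos)) sample.int(4L, length(pos), replace = TRUE)
                else integer(0),
      pathway = path[o]
    )
  }
  out
}

#' Simulate a table of FTL pollen tetrads
#'
#' Generates `n_tetrads` three-colour (or two-colour) tetrads from the
#' crossover model in `config`: Class I gamma-renewal events superposed with
#' Class II Poisson events on the marker span, random non-sister chromatid
#' pairing per event, and marker inheritance by crossover parity.
#'
#' @param config A [sim_config()].
#' @return A long-format data frame of class `ftl_tetrads` with columns
#'   `tetrad_id`, `grain` (1-4), and one 0/1 presence column per fluorophore.
#'   Attribute `"truth"` holds the simulated crossover counts per interval
#'   per tetrad; attribute `"dropped"` the number of tetrads removed by the
#'   viability filter.
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 50, seed = 1))
#' head(tt)
#' @export
simulate_ftl_tetrads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_tetrads
  m <- (config$marker_positions_cM - config$marker_positions_cM[1]) / 100
  span <- m[length(m)]
  ev <- draw_bivalent_events(n, span, config$interference_shape,
                             config$class2_fraction)
  nm <- length(m)
  grains <- matrix(0L, nrow = 4L * n, ncol = nm)
  truth <- matrix(0L, nrow = n, ncol = nm - 1L)
  for (i in seq_len(n)) {
    tet <- events_to_tetrad(ev[[i]], m, length_m = span)
    grains[(4L * i - 3L):(4L * i), ] <- tet
    truth[i, ] <- vapply(seq_len(nm - 1L), function(j)
      sum(ev[[i]]$position >= m[j] & ev[[i]]$position < m[j + 1L]), integer(1))
  }
  tab <- data.frame(tetrad_id = rep(seq_len(n), each = 4L),
                    grain = rep(1:4, n))
  for (j in seq_len(nm)) tab[[config$marker_names[j]]] <- grains[, j]
  dropped <- 0L
  if (config$viability_filter && !is.null(tab$unbalanced)) {
    bad <- unique(tab$tetrad_id[tab$unbalanced == 1L])
    dropped <- length(bad)
    tab <- tab[!(tab$tetrad_id %in% bad), , drop = FALSE]
  }
  structure(tab,
            truth = as.data.frame(truth,
                                  col.names = paste0("co_i",
                                                     seq_len(nm - 1L))),
            dropped = dropped,
            marker_names = config$marker_names,
            class = c("ftl_tetrads", "data.frame"))
}

#' Simulate per-cell chiasma and univalent counts
#'
#' For each cell, crossover counts are drawn independently on each of the
#' five bivalents from the two-pathway model; the chiasma count is their sum.
#' With `obligate_co = TRUE` (the default for chiasma simulation) each
#' bivalent is resampled until it carries at least one crossover, which
#' inflates the marginal rate above 2 per Morgan. Without it, a bivalent
#' with no crossover yields a pair of univalents.
#'
#' @param config A [sim_config()]; uses `n_cells`, `bivalent_lengths_cM`,
#'   `interference_shape`, `class2_fraction`, `genotype`, `seed`.
#' @param obligate_co Force at least one crossover per bivalent by rejection;
#'   defaults to `TRUE` (pass `config$obligate_co` to follow the config
#'   flag instead).
#' @return Data frame of class `chiasma_sample` with columns `cell_id`,
#'   `chiasmata`, `univalents`, `genotype`.
#' @examples
#' cs <- simulate_chiasma_counts(sim_config(n_cells = 20, obligate_co = TRUE,
#'                                          seed = 1))
#' summarize_chiasma(cs)
#' @export
simulate_chiasma_counts <- function(config, obligate_co = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  obligate_co <- isTRUE(obligate_co)
  n <- config$n_cells
  shape <- config$interference_shape
  class2 <- config$class2_fraction
  lens <- config$bivalent_lengths_cM / 100
  per_biv <- matrix(0L, nrow = n, ncol = length(lens))
  for (b in seq_along(lens)) {
    cnt <- renewal_counts(n, lens[b], shape, 2 * (1 - class2)) +
      (if (class2 > 0) stats::rpois(n, 2 * class2 * lens[b]) else 0L)
    if (obligate_co) {
      zero <- which(cnt == 0L)
      while (length(zero)) {
        redraw <- renewal_counts(length(zero), lens[b], shape,
                                 2 * (1 - class2)) +
          (if (class2 > 0) stats::rpois(length(zero), 2 * class2 * lens[b])
           else 0L)
        cnt[zero] <- redraw
        zero <- zero[redraw == 0L]
      }
    }
    per_biv[, b] <- cnt
  }
  structure(data.frame(
    cell_id = seq_len(n),
    chiasmata = as.integer(rowSums(per_biv)),
    univalents = if (obligate_co) 0L
                 else as.integer(2L * rowSums(per_biv == 0L)),
    genotype = config$genotype,
    stringsAsFactors = FALSE
  ), class = c("chiasma_sample", "data.frame"))
}

#' Simulate a bead-calibrated intensity dataset
#'
#' Emulates paired ROI measurements of an axis protein signal on synapsed and
#' unsynapsed chromosome regions, co-imaged with calibration microspheres.
#' Each cell has a multiplicative gain (illumination/exposure) shared by its
#' ROIs and beads, so dividing by the bead mean removes it exactly. On the
#' normalised scale the unsynapsed signal is centred at 1 and the synapsed
#' signal at `1 - true_reduction_fraction`, each with additive Gaussian noise
#' of standard deviation `noise`.
#'
#' @param n_cells Number of cells (paired measurements).
#' @param true_reduction_fraction Fractional reduction on synapsed regions,
#'   in `[0, 1)`; 0 = no change.
#' @param noise Standard deviation of measurement noise on the normalised
#'   scale.
#' @param bead_mean True microsphere grey-scale intensity before gain.
#' @param gain_sd Standard deviation of the per-cell log-normal gain.
#' @param seed Optional integer seed.
#' @return Data frame of class `intensity_table` with columns `cell_id`,
#'   `region` (`"synapsed"`/`"unsynapsed"`), `roi_mean`, `bead_mean`.
#' @examples
#' it <- simulate_intensity_dataset(23, 0.67, noise = 0.1, seed = 1)
#' paired_reduction(it)
#' @export
simulate_intensity_dataset <- function(n_cells, true_reduction_fraction,
                                       noise = 0.1, bead_mean = 100,
                                       gain_sd = 0.3, seed = NULL) {
  if (true_reduction_fraction < 0 || true_reduction_fraction >= 1)
    stop("`true_reduction_fraction` must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gain <- exp(stats::rnorm(n_cells, 0, gain_sd))
  # grey-scale intensities cannot go below zero
  unsyn <- pmax(1 + stats::rnorm(n_cells, 0, noise), 0)
  syn <- pmax((1 - true_reduction_fraction) + stats::rnorm(n_cells, 0, noise),
              0)
  structure(data.frame(
    cell_id = rep(seq_len(n_cells), times = 2L),
    region = rep(c("synapsed", "unsynapsed"), each = n_cells),
    roi_mean = c(syn, unsyn) * rep(gain * bead_mean, 2L),
    bead_mean = rep(gain * bead_mean, 2L),
    stringsAsFactors = FALSE
  ), class = c("intensity_table", "data.frame"))
}
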