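#' Score one FTL interval in a tetrad
#'
#' A pollen grain is recombinant for the interval between two fluorescent
#' markers iff its two presence calls differ. With markers in coupling a
#' balanced tetrad has 0, 2, or 4 recombinant grains, giving the parental
#' ditype (PD), tetratype (TT), or non-parental ditype (NPD) state.
#'
#' @param tetrad Integer/logical matrix with 4 rows (grains) and one 0/1
#'   column per marker.
#' @param marker_a,marker_b Column indices or names of the two markers.
#' @return List of class `interval_state` with elements `state` (`"PD"`,
#'   `"TT"`, `"NPD"`) and `recombinant_grains` (integer vector of row
#'   indices).
#' @section Errors: a recombinant-grain count of 1 or 3 indicates a
#'   mis-scored grain; the tetrad cannot be classified and an error of class
#'   `ambiguous_tetrad` is signalled (callers such as [tally_tetrads()]
#'   exclude the tetrad and log it).
#' @examples
#' tet <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
#' interval_state(tet, 1, 2)$state  # "PD"
#' @export
interval_state <- function(tetrad, marker_a, marker_b) {
  tetrad <- as.matrix(tetrad)
  if (nrow(tetrad) != 4L)
    stop("a tetrad has exactly 4 grains", call. = FALSE)
  calls <- tetrad[, c(marker_a, marker_b), drop = FALSE]
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("marker calls must be 0/1 and complete", call. = FALSE)
  rec <- which(calls[, 1L] != calls[, 2L])
  state <- switch(as.character(length(rec)),
                  "0" = "PD", "2" = "TT", "4" = "NPD", NA_character_)
  if (is.na(state))
    stop(errorCondition(
      sprintf("ambiguous tetrad: %d recombinant grain(s) for interval (%s,%s)",
              length(rec), marker_a, marker_b),
      class = c("ambiguous_tetrad", "error", "condition")))
  structure(list(state = state, recombinant_grains = rec),
            class = "interval_state")
}

#' Canonical tetrad classes for two adjacent intervals
#'
#' The joint (interval 1, interval 2) state, with tetratype-by-tetratype
#' tetrads subdivided by how many grains are recombinant in both intervals
#' (2, 1, or 0 — the two-, three-, and four-strand double crossovers),
#' yields 11 distinguishable classes from three-colour scoring; letters
#' follow the conventional A-L chart of FTL tetrad types, with `L` reserved
#' for patterns outside this enumeration (`OTHER`). Analyses depend only on
#' joint states, never on the letters.
#'
#' @return Data frame with columns `label`, `state1`, `state2`, `overlap`
#'   (NA except for the TT/TT subtypes).
#' @examples
#' tetrad_class_table()
#' @export
tetrad_class_table <- function() {
  data.frame(
    label  = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"),
    state1 = c("PD", "TT", "PD", "NPD", "PD", "TT", "TT", "TT", "TT",
               "NPD", "NPD"),
    state2 = c("PD", "PD", "TT", "PD", "NPD", "TT", "TT", "TT", "NPD",
               "TT", "NPD"),
    overlap = c(NA, NA, NA, NA, NA, 2L, 1L, 0L, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Classify a three-colour tetrad into its joint class
#'
#' @param tetrad 4 x 3 matrix of 0/1 fluorophore calls (grains x markers in
#'   map order).
#' @return List of class `tetrad_class` with `state1`, `state2`, `overlap`
#'   (number of grains recombinant in both intervals; NA unless both states
#'   are TT), and `label` (letter code, or `"OTHER"`).
#' @inheritSection interval_state Errors
#' @examples
#' tet <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1), c(0, 0, 0))
#' classify_tetrad(tet)$label
#' @export
classify_tetrad <- function(tetrad) {
  tetrad <- as.matrix(tetrad)
  if (ncol(tetrad) != 3L)
    stop("three scored markers are required", call. = FALSE)
  s1 <- interval_state(tetrad, 1L, 2L)
  s2 <- interval_state(tetrad, 2L, 3L)
  overlap <- NA_integer_
  if (s1$state == "TT" && s2$state == "TT")
    overlap <- length(intersect(s1$recombinant_grains, s2$recombinant_grains))
  key <- tetrad_class_table()
  hit <- key$state1 == s1$state & key$state2 == s2$state &
    (is.na(key$overlap) | (!is.na(overlap) & key$overlap == overlap))
  label <- if (any(hit)) key$label[which(hit)[1L]] else "OTHER"
  structure(list(state1 = s1$state, state2 = s2$state,
                 overlap = overlap, label = label),
            class = "tetrad_class")
}

# Extract the 4 x m call matrix of one tetrad from a long table.
tetrad_matrix <- function(tab, id, marker_cols) {
  rows <- tab[tab$tetrad_id == id, , drop = FALSE]
  as.matrix(rows[order(rows$grain), marker_cols, drop = FALSE])
}

marker_columns <- function(tab) {
  setdiff(names(tab), c("tetrad_id", "grain", "unbalanced", "genotype"))
}

#' Tally tetrad classes over a table
#'
#' Classifies every tetrad in a long-format table and accumulates the joint
#' class counts; ambiguous tetrads (odd recombinant-grain counts from
#' mis-scoring) are excluded and logged rather than guessed.
#'
#' @param tab Long-format tetrad table (`tetrad_id`, `grain`, one 0/1 column
#'   per fluorophore) as produced by [simulate_ftl_tetrads()] or
#'   [read_tetrad_table()].
#' @return Object of class `tetrad_tally`: a list with `joint` (data frame
#'   `state1`, `state2`, `overlap`, `label`, `count`), `n` (classified
#'   tetrads), and `excluded` (data frame of `tetrad_id`, `reason`).
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 200, seed = 1))
#' tally_tetrads(tt)
#' @export
tally_tetrads <- function(tab) {
  mk <- marker_columns(tab)
  if (length(mk) != 3L)
    stop("tallying needs exactly 3 marker columns, found: ",
         paste(mk, collapse = ", "), call. = FALSE)
  if (!nrow(tab)) stop("empty tetrad table", call. = FALSE)
  calls <- as.matrix(tab[, mk])
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("marker calls must be 0/1 and complete", call. = FALSE)
  grains_per <- table(tab$tetrad_id)
  if (any(grains_per != 4L))
    stop("every tetrad needs exactly 4 grains; offending tetrad_id: ",
         paste(utils::head(names(grains_per)[grains_per != 4L], 5),
               collapse = ", "), call. = FALSE)
  # vectorised classification: per-grain recombination indicators summed
  # within tetrads (rowsum orders groups by sorted unique id)
  g <- tab$tetrad_id
  r1 <- as.integer(calls[, 1L] != calls[, 2L])
  r2 <- as.integer(calls[, 2L] != calls[, 3L])
  k1 <- rowsum(r1, g)[, 1L]
  k2 <- rowsum(r2, g)[, 1L]
  ov <- rowsum(r1 * r2, g)[, 1L]
  ambiguous <- k1 %% 2L == 1L | k2 %% 2L == 1L
  st <- function(k) c("PD", NA, "TT", NA, "NPD")[k + 1L]
  s1 <- st(k1); s2 <- st(k2)
  is_ttt <- !ambiguous & s1 == "TT" & s2 == "TT"
  key <- tetrad_class_table()
  labels <- rep(NA_character_, length(k1))
  for (i in seq_len(nrow(key))) {
    sel <- if (is.na(key$overlap[i]))
      !ambiguous & s1 == key$state1[i] & s2 == key$state2[i] & !is_ttt
    else is_ttt & ov == key$overlap[i]
    labels[sel] <- key$label[i]
  }
  labels[!ambiguous & is.na(labels)] <- "OTHER"
  joint <- rbind(key, data.frame(label = "OTHER", state1 = NA, state2 = NA,
                                 overlap = NA))
  joint$count <- as.integer(
    vapply(joint$label, function(l) sum(labels == l, na.rm = TRUE),
           integer(1)))
  ids <- names(k1)
  structure(list(joint = joint,
                 n = sum(joint$count),
                 excluded = data.frame(
                   tetrad_id = ids[ambiguous],
                   reason = sprintf(
                     "odd recombinant-grain count (%d, %d)",
                     k1[ambiguous], k2[ambiguous]),
                   stringsAsFactors = FALSE)),
            class = "tetrad_tally")
}

#' @export
print.tetrad_tally <- function(x, ...) {
  cat("Tetrad class tally (", x$n, " classified, ",
      nrow(x$excluded), " excluded)\n", sep = "")
  shown <- x$joint[x$joint$count > 0 | x$joint$label != "OTHER", ]
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Marginal PD/TT/NPD counts for one interval
#'
#' @param tally A [tally_tetrads()] result.
#' @param interval 1 or 2.
#' @return Object of class `interval_counts`: list with `PD`, `TT`, `NPD`,
#'   `n`.
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 200, seed = 1))
#' interval_counts(tally_tetrads(tt), 1)
#' @export
interval_counts <- function(tally, interval = 1L) {
  stopifnot(inherits(tally, "tetrad_tally"), interval %in% 1:2)
  st <- tally$joint[[paste0("state", interval)]]
  cnt <- tally$joint$count
  ok <- !is.na(st)
  out <- list(PD = sum(cnt[ok & st == "PD"]),
              TT = sum(cnt[ok & st == "TT"]),
              NPD = sum(cnt[ok & st == "NPD"]))
  out$n <- out$PD + out$TT + out$NPD
  structure(out, class = "interval_counts")
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf("PD %d  TT %d  NPD %d  (n = %d)\n", x$PD, x$TT, x$NPD, x$n))
  invisible(x)
}
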