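# Independent brute-force oracle for tetrad patterns: composes the line
# permutations of a chiasma diagram directly (vectorised transpositions of
# path occupancy), instead of the package's per-path event scan.

oracle_pairings <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))

# p1, p2: pairing index (1-4) of the single CO in interval 1 / interval 2,
# or NULL for no CO.  Returns the 4 x 3 grain-by-marker 0/1 matrix for
# paths started on chromatids 1..4.
oracle_tetrad <- function(p1 = NULL, p2 = NULL) {
  occ <- 1:4
  apply_co <- function(occ, pi) {
    pr <- oracle_pairings[[pi]]
    ifelse(occ == pr[1L], pr[2L], ifelse(occ == pr[2L], pr[1L], occ))
  }
  tet <- matrix(NA_integer_, 4L, 3L)
  tet[, 1L] <- as.integer(occ <= 2L)
  if (!is.null(p1)) occ <- apply_co(occ, p1)
  tet[, 2L] <- as.integer(occ <= 2L)
  if (!is.null(p2)) occ <- apply_co(occ, p2)
  tet[, 3L] <- as.integer(occ <= 2L)
  colnames(tet) <- c("c1", "c2", "c3")
  tet
}

# Build the implementation-side event list for the same configuration.
impl_events <- function(p1 = NULL, p2 = NULL, m = c(0, 0.1, 0.2)) {
  pos <- numeric(0); pr <- integer(0)
  if (!is.null(p1)) { pos <- c(pos, mean(m[1:2])); pr <- c(pr, p1) }
  if (!is.null(p2)) { pos <- c(pos, mean(m[2:3])); pr <- c(pr, p2) }
  data.frame(position = pos, pairing = pr,
             pathway = rep("interfering", length(pos)))
}

# Long-format table from a list of 4 x k tetrad matrices.
tetrads_to_table <- function(mats) {
  do.call(rbind, lapply(seq_along(mats), function(i) {
    d <- as.data.frame(mats[[i]])
    cbind(data.frame(tetrad_id = i, grain = 1:4), d)
  }))
}
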