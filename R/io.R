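sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a tetrad fluorescence table
#'
#' Reads a long-format CSV/TSV of scored pollen tetrads: columns
#' `tetrad_id`, `grain`, then one 0/1 presence column per fluorophore.
#' Tetrads with missing grains, duplicated grains, or non-binary calls are
#' rejected (not silently fixed); rejected tetrad ids and reasons are
#' attached as the `"rejected"` attribute and reported in a message.
#'
#' @param path File path; delimiter is sniffed from the header (comma or
#'   tab) unless `delim` is given.
#' @param delim Optional explicit field delimiter.
#' @return Data frame of class `ftl_tetrads` containing the valid tetrads.
#' @examples
#' tt <- simulate_ftl_tetrads(sim_config(n_tetrads = 10, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_tetrad_table(tt, f)
#' identical(nrow(read_tetrad_table(f)), nrow(tt))
#' @export
read_tetrad_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  if (!all(c("tetrad_id", "grain") %in% names(tab)))
    stop("malformed header: need columns `tetrad_id` and `grain`",
         call. = FALSE)
  mk <- marker_columns(tab)
  if (!length(mk))
    stop("no fluorophore columns found", call. = FALSE)
  bad_id <- character(0); bad_why <- character(0)
  flag <- function(ids, why) {
    bad_id <<- c(bad_id, as.character(ids))
    bad_why <<- c(bad_why, rep(why, length(ids)))
  }
  calls <- as.matrix(tab[, mk, drop = FALSE])
  inset <- matrix(calls %in% c(0, 1), nrow = nrow(calls))
  ok_call <- rowSums(is.na(calls) | !inset) == 0L
  if (any(!ok_call)) flag(unique(tab$tetrad_id[!ok_call]),
                          "non-binary or missing fluorophore call")
  per <- table(tab$tetrad_id)
  if (any(per != 4L)) flag(names(per)[per != 4L], "tetrad without 4 grains")
  dup <- tapply(tab$grain, tab$tetrad_id, function(g) anyDuplicated(g) > 0L)
  if (any(dup)) flag(names(dup)[dup], "duplicated grain index")
  bad <- unique(bad_id)
  keep <- !(as.character(tab$tetrad_id) %in% bad)
  if (length(bad))
    message(length(bad), " tetrad(s) rejected: ",
            paste(utils::head(unique(paste0(bad_id, " (", bad_why, ")")), 5L),
                  collapse = "; "))
  out <- tab[keep, , drop = FALSE]
  if (!nrow(out)) stop("no valid tetrads in ", path, call. = FALSE)
  structure(out,
            rejected = data.frame(tetrad_id = bad_id, reason = bad_why,
                                  stringsAsFactors = FALSE),
            class = c("ftl_tetrads", "data.frame"))
}

#' Write a tetrad table to CSV
#'
#' @param x Tetrad table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell chiasma count table
#'
#' CSV/TSV with columns `cell_id`, `chiasmata`, and optionally `univalents`
#' (even, univalents come in pairs) and `genotype`.
#'
#' @inheritParams read_tetrad_table
#' @return Data frame of class `chiasma_sample`.
#' @export
read_chiasma_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "chiasmata") %in% names(tab)))
    stop("malformed header: need columns `cell_id` and `chiasmata`",
         call. = FALSE)
  if (any(tab$chiasmata < 0) || any(tab$chiasmata %% 1 != 0))
    stop("`chiasmata` must be non-negative integers", call. = FALSE)
  if (!is.null(tab$univalents) && any(tab$univalents %% 2 != 0))
    stop("`univalents` must be even", call. = FALSE)
  if (is.null(tab$univalents)) tab$univalents <- NA_integer_
  if (is.null(tab$genotype)) tab$genotype <- "unknown"
  structure(tab, class = c("chiasma_sample", "data.frame"))
}

#' Read an ROI intensity table
#'
#' CSV/TSV with columns `cell_id`, `region` (`synapsed`/`unsynapsed`),
#' `roi_mean`, `bead_mean` (grey-scale values).
#'
#' @inheritParams read_tetrad_table
#' @return Data frame of class `intensity_table`.
#' @export
read_intensity_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "region", "roi_mean", "bead_mean")
  if (!all(need %in% names(tab)))
    stop("malformed header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$region %in% c("synapsed", "unsynapsed")))
    stop("`region` must be 'synapsed' or 'unsynapsed'", call. = FALSE)
  if (any(tab$bead_mean <= 0))
    stop("`bead_mean` must be positive", call. = FALSE)
  structure(tab, class = c("intensity_table", "data.frame"))
}

#' Write a generic results table to CSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
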