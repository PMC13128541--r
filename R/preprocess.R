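#' Rarefy a count table to even sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via `vegan::rrarefy`) so that every retained sample has
#' exactly `depth` reads. Samples with fewer than `depth` total reads are
#' dropped and reported, matching the standard practice of standardising
#' depth before diversity and network analysis.
#'
#' @param table A [count_table()].
#' @param depth Target depth (reads per sample), a positive integer.
#' @param seed Integer seed; the subsampling is reproducible from it.
#' @return A `count_table` whose columns all sum to `depth`. Dropped sample
#'   ids are attached as attribute `"dropped"` and reported via a message.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  assert_scalar_number(depth, "depth", lower = 1)
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  keep <- names(totals)[totals >= depth]
  dropped <- setdiff(colnames(table$counts), keep)
  if (length(keep) == 0) {
    abort(sprintf("all %d samples are below the rarefaction depth %d.",
                  ncol(table$counts), depth))
  }
  if (length(dropped) > 0) {
    inform(sprintf("rarefy: dropped %d sample(s) below depth %d: %s",
                   length(dropped), depth, paste(dropped, collapse = ", ")))
  }
  sub <- table$counts[, keep, drop = FALSE]
  rare <- with_seed(seed, t(vegan::rrarefy(t(sub), sample = depth)))
  out <- count_table(rare,
                     table$sample_meta[table$sample_meta$sample_id %in% keep, ],
                     table$taxon_meta)
  attr(out, "dropped") <- dropped
  out
}

#' Convert counts to per-sample relative abundances
#'
#' Each cell is divided by its sample's total count; columns of an empty
#' sample stay zero (and are flagged).
#'
#' @param table A `count_table`, or a bare numeric matrix (zOTU x sample).
#' @return A numeric matrix of the same shape whose non-empty columns sum
#'   to 1, with class attribute `rel_abund`.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  totals <- colSums(counts)
  empty <- names(totals)[totals == 0]
  if (length(empty) > 0) {
    inform(paste0("relative_abundance: all-zero sample(s): ",
                  paste(empty, collapse = ", ")))
  }
  scale <- ifelse(totals > 0, totals, 1)
  out <- sweep(counts, 2, scale, "/")
  class(out) <- c("rel_abund", class(out))
  out
}

#' Per-kingdom relative abundances
#'
#' Divides each zOTU's counts by its own kingdom's per-sample totals.
#' Each kingdom is sequenced (and rarefied) as its own library, so
#' abundances are compositional within a kingdom; normalising per kingdom
#' also keeps the kingdoms' independent library-depth fluctuations from
#' acting as a shared correlation-inflating factor across all taxa of a
#' kingdom.
#'
#' @param table A `count_table` with kingdom labels in its taxon metadata.
#' @return A numeric matrix of within-kingdom relative abundances, same
#'   shape as the counts.
#' @export
kingdom_relative_abundance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  out <- counts
  for (k in unique(table$taxon_meta$kingdom)) {
    rows <- table$taxon_meta$zotu_id[table$taxon_meta$kingdom == k]
    tot <- colSums(counts[rows, , drop = FALSE])
    out[rows, ] <- sweep(counts[rows, , drop = FALSE], 2,
                         ifelse(tot > 0, tot, 1), "/")
  }
  out
}

#' Filter zOTUs by mean relative abundance
#'
#' Retains zOTUs whose mean relative abundance across the table's samples is
#' strictly greater than `threshold`. The default 1e-4 (0.01%) is the usual
#' rare-taxon screen applied before network construction; it is computed on
#' the mean across the analysis dataset's samples.
#'
#' @param table A `count_table`.
#' @param threshold Fraction in `[0, 1)`; default `1e-4`.
#' @return The filtered `count_table`; the number of retained zOTUs is
#'   reported via a message. The filter is idempotent.
#' @export
filter_by_mean_rel_abund <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    abort("`threshold` must be in [0, 1).")
  }
  rel <- relative_abundance(table)
  keep <- rowMeans(rel) > threshold
  if (!any(keep)) {
    abort(sprintf(
      "no zOTU exceeds mean relative abundance %g; review the threshold.",
      threshold))
  }
  inform(sprintf("filter_by_mean_rel_abund: retained %d / %d zOTUs (mean rel. abund > %g)",
                 sum(keep), nrow(rel), threshold))
  subset_count_table(table, taxa = rownames(table$counts)[keep])
}

#' Per-sample Shannon diversity
#'
#' `H = -sum(p_i * log(p_i))` over taxa present in the sample, natural
#' logarithm (via `vegan::diversity`). Empty samples get `NA`.
#'
#' @param table A `count_table`.
#' @return A tibble with columns `sample_id`, `shannon`, joined with the
#'   sample metadata.
#' @export
shannon_diversity <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  h <- vegan::diversity(t(table$counts), index = "shannon")
  h[totals == 0] <- NA_real_
  if (any(totals == 0)) {
    inform(paste0("shannon_diversity: empty sample(s) reported as NA: ",
                  paste(names(totals)[totals == 0], collapse = ", ")))
  }
  tibble(sample_id = colnames(table$counts), shannon = unname(h)) |>
    left_join(table$sample_meta, by = "sample_id")
}
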