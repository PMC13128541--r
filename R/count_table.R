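#' Construct a zOTU count table
#'
#' The universal input of the pipeline: a non-negative integer matrix of
#' zOTU-by-sample read counts together with per-sample and per-taxon
#' metadata. Sample metadata records the experimental design
#' (compartment, drought treatment, growth stage, replicate); taxon
#' metadata records the kingdom (prokaryote / fungus / protist) and a
#' taxonomy string.
#'
#' @param counts Integer matrix, rows = zOTUs (rownames required),
#'   columns = samples (colnames required). All cells must be
#'   non-negative integers.
#' @param sample_meta Tibble with columns `sample_id`, `compartment`,
#'   `treatment`, `stage`, `replicate`, covering every column of `counts`.
#' @param taxon_meta Tibble with columns `zotu_id`, `kingdom`, `taxonomy`,
#'   covering every row of `counts`.
#'
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_meta, taxon_meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have zOTU rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("zOTU ids must be unique.")
  if (anyDuplicated(colnames(counts))) abort("sample ids must be unique.")
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cell <- bad[1, ]
    abort(sprintf(
      "non-integer or negative count at zOTU '%s', sample '%s' (value %s).",
      rownames(counts)[cell[1]], colnames(counts)[cell[2]],
      format(counts[cell[1], cell[2]])))
  }
  storage.mode(counts) <- "double" # integer counts, double storage for depth sums
  sample_meta <- as_tibble(sample_meta)
  taxon_meta <- as_tibble(taxon_meta)
  if (!"sample_id" %in% names(sample_meta)) abort("`sample_meta` needs a `sample_id` column.")
  if (!"zotu_id" %in% names(taxon_meta)) abort("`taxon_meta` needs a `zotu_id` column.")
  missing_s <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("sample metadata missing ids: ", paste(missing_s, collapse = ", ")))
  }
  missing_t <- setdiff(rownames(counts), taxon_meta$zotu_id)
  if (length(missing_t) > 0) {
    abort(paste0("taxon metadata missing ids: ", paste(missing_t, collapse = ", ")))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  taxon_meta <- taxon_meta[match(rownames(counts), taxon_meta$zotu_id), ]
  structure(
    list(counts = counts, sample_meta = sample_meta, taxon_meta = taxon_meta),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d zOTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("kingdom" %in% names(x$taxon_meta)) {
    k <- table(x$taxon_meta$kingdom)
    cat("  kingdoms:", paste(sprintf("%s=%d", names(k), k), collapse = ", "), "\n")
  }
  if ("treatment" %in% names(x$sample_meta)) {
    tr <- table(x$sample_meta$treatment)
    cat("  treatments:", paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Tidy a count table into long format
#'
#' @param x A `count_table`.
#' @param ... Unused.
#' @return A tibble with one row per (zOTU, sample) pair carrying the count
#'   and the joined sample/taxon metadata.
#' @export
tidy.count_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "zotu_id") |>
    pivot_longer(-"zotu_id", names_to = "sample_id", values_to = "count")
  long |>
    left_join(x$taxon_meta, by = "zotu_id") |>
    left_join(x$sample_meta, by = "sample_id")
}

#' Subset a count table by samples and/or taxa
#'
#' @param table A `count_table`.
#' @param samples Character vector of sample ids to keep (default: all).
#' @param taxa Character vector of zOTU ids to keep (default: all).
#' @return A `count_table` restricted to the requested rows/columns, in the
#'   requested order.
#' @export
subset_count_table <- function(table, samples = NULL, taxa = NULL) {
  stopifnot(inherits(table, "count_table"))
  samples <- samples %||% colnames(table$counts)
  taxa <- taxa %||% rownames(table$counts)
  bad_s <- setdiff(samples, colnames(table$counts))
  if (length(bad_s) > 0) abort(paste0("unknown sample ids: ", paste(bad_s, collapse = ", ")))
  bad_t <- setdiff(taxa, rownames(table$counts))
  if (length(bad_t) > 0) abort(paste0("unknown zOTU ids: ", paste(bad_t, collapse = ", ")))
  count_table(
    table$counts[taxa, samples, drop = FALSE],
    table$sample_meta[table$sample_meta$sample_id %in% samples, ],
    table$taxon_meta[table$taxon_meta$zotu_id %in% taxa, ]
  )
}

#' Read a count table and its metadata from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of zOTU ids. Metadata files are plain TSVs keyed by
#' `sample_id` / `zotu_id`.
#'
#' @param counts_file Path to the zOTU x sample matrix TSV.
#' @param sample_meta_file Path to the sample metadata TSV.
#' @param taxon_meta_file Path to the taxon metadata TSV.
#' @return A `count_table`. Row and column order follow the files.
#' @export
read_count_table <- function(counts_file, sample_meta_file, taxon_meta_file) {
  for (f in c(counts_file, sample_meta_file, taxon_meta_file)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  mat_df <- readr::read_tsv(counts_file, show_col_types = FALSE)
  counts <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(counts) <- as.character(mat_df[[1]])
  sm <- readr::read_tsv(sample_meta_file, show_col_types = FALSE)
  tm <- readr::read_tsv(taxon_meta_file, show_col_types = FALSE)
  count_table(counts, sm, tm)
}

#' Write a count table and its metadata to TSV files
#'
#' Integer tables round-trip bit-exactly through [read_count_table()].
#'
#' @param table A `count_table`.
#' @param counts_file,sample_meta_file,taxon_meta_file Output paths.
#' @return The input, invisibly.
#' @export
write_count_table <- function(table, counts_file, sample_meta_file,
                              taxon_meta_file) {
  stopifnot(inherits(table, "count_table"))
  out <- as_tibble(table$counts, rownames = "zotu_id")
  readr::write_tsv(out, counts_file)
  readr::write_tsv(table$sample_meta, sample_meta_file)
  readr::write_tsv(table$taxon_meta, taxon_meta_file)
  invisible(table)
}
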