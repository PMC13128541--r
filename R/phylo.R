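#' Patristic distance matrix from a tree
#'
#' Pairwise tip-to-tip distances along the branches (via
#' `ape::cophenetic.phylo`); a symmetric non-negative matrix with zero
#' diagonal. Square distance-matrix TSVs are accepted as-is elsewhere.
#'
#' @param tree An `ape::phylo` tree.
#' @return The patristic distance matrix over the tree's tips.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}

check_dist <- function(dist) {
  dist <- unclass(as.matrix(dist))
  if (nrow(dist) != ncol(dist)) abort("distance matrix must be square.")
  if (max(abs(dist - t(dist))) > 1e-8) abort("distance matrix must be symmetric.")
  if (any(dist < 0)) abort("distances must be non-negative.")
  dist
}

#' Mean nearest taxon distance (MNTD)
#'
#' The mean, over the taxa present in a community, of each taxon's
#' distance to its nearest other present taxon. Presence-based
#' (unweighted), the conventional default for nearest-taxon statistics.
#'
#' @param community Character vector of present taxa (>= 2), drawn from
#'   the distance matrix's taxon pool.
#' @param dist Symmetric patristic (or arbitrary) distance matrix with
#'   named rows/columns.
#' @return The MNTD (scalar).
#' @export
mntd <- function(community, dist) {
  dist <- check_dist(dist)
  community <- unique(community)
  if (length(community) < 2) abort("MNTD needs at least 2 present taxa.")
  missing <- setdiff(community, rownames(dist))
  if (length(missing) > 0) {
    abort(paste0("taxa absent from the distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  d <- dist[community, community, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Nearest taxon index (NTI)
#'
#' Standardised effect size of the observed MNTD against a taxa-label
#' shuffling null: each null draw relabels the distance matrix's taxa
#' (equivalently, draws a random same-sized community from the pool), and
#' `NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)`. NTI > 2 is
#' annotated as phylogenetic clustering (co-occurring taxa are closer
#' relatives than expected by chance). When the null sd is 0 — e.g. the
#' community is the entire pool, so every relabelling returns the same
#' MNTD — NTI is 0 and flagged.
#'
#' @param community Character vector of present taxa.
#' @param dist Distance matrix over the taxon pool.
#' @param n_null Null randomisations (default 999).
#' @param seed Integer seed.
#' @return A one-row tibble: `mntd_obs`, `null_mean`, `null_sd`, `nti`,
#'   `n_null`, `clustering` (`nti > 2`).
#' @export
nti <- function(community, dist, n_null = 999, seed = 1L) {
  dist <- check_dist(dist)
  community <- unique(community)
  pool <- rownames(dist)
  if (!all(community %in% pool)) {
    abort("community taxa must be drawn from the distance matrix's pool.")
  }
  obs <- mntd(community, dist)
  k <- length(community)
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    mntd(sample(pool, k), dist)
  }, numeric(1)))
  mu <- mean(nulls)
  s <- stats::sd(nulls)
  if (s == 0) {
    inform("nti: null sd is 0 (community may be the full taxon pool); NTI set to 0.")
    val <- 0
  } else {
    val <- -(obs - mu) / s
  }
  tibble(mntd_obs = obs, null_mean = mu, null_sd = s, nti = val,
         n_null = as.integer(n_null), clustering = val > 2)
}

#' NTI per sample of a count table
#'
#' Applies [nti()] to each sample's present taxa (count > 0), against a
#' shared distance matrix. Samples with fewer than 2 present pool taxa are
#' skipped with a message.
#'
#' @param table A [count_table()].
#' @param dist Distance matrix (or an `ape::phylo` tree) covering the
#'   table's taxa.
#' @param n_null,seed See [nti()].
#' @return A tibble with one row per scored sample: `sample_id` plus the
#'   [nti()] columns, joined with sample metadata.
#' @export
nti_per_sample <- function(table, dist, n_null = 999, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (inherits(dist, "phylo")) dist <- patristic_distances(dist)
  dist <- check_dist(dist)
  pool <- rownames(dist)
  rows <- purrr::imap(
    stats::setNames(seq_len(ncol(table$counts)), colnames(table$counts)),
    function(j, sid) {
      present <- rownames(table$counts)[table$counts[, j] > 0]
      present <- intersect(present, pool)
      if (length(present) < 2) {
        inform(sprintf("nti_per_sample: sample '%s' has < 2 pool taxa; skipped.", sid))
        return(NULL)
      }
      nti(present, dist, n_null = n_null,
          seed = derive_seed(seed, j)) |>
        mutate(sample_id = sid, .before = 1)
    })
  bind_rows(rows) |> left_join(table$sample_meta, by = "sample_id")
}
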