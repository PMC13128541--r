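#' Zi-Pi node roles
#'
#' Within-module degree z-score `Zi = (k_is - mean_s(k)) / sd_s(k)` (links
#' of node `i` into its own module `s`, standardised over the module's
#' members, n-1 sd; a zero sd gives `Zi = 0`) and participation
#' coefficient `Pi = 1 - sum_t (k_it / k_i)^2` over modules `t`
#' (`Pi = 0` for an isolated node, flagged). Roles follow the conventional
#' thresholds, applied in fixed precedence because the printed rules
#' overlap at the boundary: network hub (`Zi >= 2.5` and `Pi >= 0.62`)
#' first, then module hub (`Zi > 2.5`), then connector (`Pi > 0.62`),
#' otherwise peripheral. Module hubs, connectors and network hubs are the
#' keystone taxa.
#'
#' @param net A `cooccurrence_network` or `igraph` graph.
#' @param modules Module assignment tibble (`node`, `module`) from
#'   [detect_modules()].
#' @return A `node_role_table` tibble: `node`, `module`, `degree`, `zi`,
#'   `pi`, `role`, `keystone`.
#' @export
zi_pi <- function(net, modules) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!all(nm %in% modules$node)) abort("`modules` must cover every network node.")
  mod <- modules$module[match(nm, modules$node)]
  a <- as_adjacency(g)
  # k[i, t]: links of node i into module t
  mods <- sort(unique(mod))
  k_mat <- vapply(mods, function(t) rowSums(a[, mod == t, drop = FALSE]), numeric(nrow(a)))
  if (is.null(dim(k_mat))) k_mat <- matrix(k_mat, nrow = nrow(a))
  k_tot <- rowSums(k_mat)
  k_own <- k_mat[cbind(seq_along(nm), match(mod, mods))]
  zi <- vapply(seq_along(nm), function(i) {
    own <- which(mod == mod[i])
    if (length(own) < 2) return(0)
    s <- stats::sd(k_own[own])
    if (s == 0) 0 else (k_own[i] - mean(k_own[own])) / s
  }, numeric(1))
  pi_val <- ifelse(k_tot > 0, 1 - rowSums((k_mat / pmax(k_tot, 1))^2), 0)
  if (any(k_tot == 0)) {
    inform(sprintf("zi_pi: %d node(s) of degree 0; their Pi is defined as 0.",
                   sum(k_tot == 0)))
  }
  role <- case_when(
    zi >= 2.5 & pi_val >= 0.62 ~ "network hub",
    zi > 2.5 & pi_val <= 0.62 ~ "module hub",
    zi <= 2.5 & pi_val > 0.62 ~ "connector",
    .default = "peripheral")
  out <- tibble(node = nm, module = mod, degree = unname(k_tot),
                zi = unname(zi), pi = unname(pi_val), role = unname(role),
                keystone = unname(role != "peripheral"))
  class(out) <- c("node_role_table", class(out))
  out
}

#' Specificity-occupancy (SPEC-OCCU) table
#'
#' Treatments are treated as habitats. Specificity of zOTU `i` for habitat
#' `h` is its mean relative abundance in `h` divided by the sum of its
#' mean relative abundances over all habitats (rows sum to 1 for any zOTU
#' detected anywhere); occupancy is the fraction of `h`'s samples in which
#' the zOTU is present (abundance > 0). Specialists are zOTUs with both
#' specificity and occupancy strictly above the thresholds that also rank
#' among the habitat's `top_n` most abundant (by mean relative abundance).
#'
#' @param abund Taxa x sample relative-abundance matrix.
#' @param habitats Named character vector mapping sample id -> habitat
#'   label (>= 2 habitats; every sample must be labelled).
#' @param top_n Abundance screen per habitat (default 500).
#' @param spec_min,occu_min Strict specialist thresholds (default 0.7).
#' @return A `spec_occu_table` tibble: `zotu_id`, `habitat`,
#'   `specificity`, `occupancy`, `abundance_rank`, `specialist`.
#' @export
spec_occu <- function(abund, habitats, top_n = 500,
                      spec_min = 0.7, occu_min = 0.7) {
  abund <- unclass(as.matrix(abund))
  if (is.null(names(habitats))) abort("`habitats` must be named by sample id.")
  unlabelled <- setdiff(colnames(abund), names(habitats))
  if (length(unlabelled) > 0) {
    abort(paste0("unlabelled samples: ", paste(unlabelled, collapse = ", ")))
  }
  hab <- habitats[colnames(abund)]
  levels <- unique(hab)
  if (length(levels) < 2) abort("need at least 2 habitats.")
  if (any(table(factor(hab, levels)) == 0)) abort("every habitat needs at least one sample.")
  mean_ab <- vapply(levels, function(h) rowMeans(abund[, hab == h, drop = FALSE]),
                    numeric(nrow(abund)))
  occ <- vapply(levels, function(h) rowMeans(abund[, hab == h, drop = FALSE] > 0),
                numeric(nrow(abund)))
  total <- rowSums(mean_ab)
  spec <- mean_ab / ifelse(total > 0, total, Inf)
  rank_ab <- apply(-mean_ab, 2, rank, ties.method = "min")
  out <- tibble(
    zotu_id = rep(rownames(abund), times = length(levels)),
    habitat = rep(levels, each = nrow(abund)),
    specificity = as.vector(spec),
    occupancy = as.vector(occ),
    abundance_rank = as.integer(rank_ab)) |>
    mutate(specialist = .data$specificity > spec_min &
             .data$occupancy > occu_min &
             .data$abundance_rank <= top_n)
  class(out) <- c("spec_occu_table", class(out))
  out
}

#' zOTUs shared across all treatment groups
#'
#' A zOTU is "detected" in a group when its total count over the group's
#' samples is positive after the network-level mean-relative-abundance
#' screen; shared zOTUs are those detected in every group. Venn region
#' counts over the groups' detected sets are reported alongside.
#'
#' @param table A [count_table()] spanning all groups.
#' @param group_col Sample-metadata column defining the groups (default
#'   `"treatment"`).
#' @param min_rel_abund Mean relative-abundance screen applied within each
#'   group (default 1e-4, as for network construction).
#' @return A list: `shared` (character vector), `detected` (named list of
#'   per-group detected sets) and `venn` (tibble `region`, `n`; regions
#'   partition the union).
#' @export
shared_taxa <- function(table, group_col = "treatment", min_rel_abund = 1e-4) {
  stopifnot(inherits(table, "count_table"))
  groups <- unique(table$sample_meta[[group_col]])
  if (length(groups) < 2) abort("need at least 2 groups.")
  detected <- lapply(groups, function(gr) {
    ids <- table$sample_meta$sample_id[table$sample_meta[[group_col]] == gr]
    sub <- subset_count_table(table, samples = ids)
    rel_k <- kingdom_relative_abundance(sub)
    keep <- rowMeans(rel_k) > min_rel_abund & rowSums(sub$counts) > 0
    rownames(sub$counts)[keep]
  })
  names(detected) <- groups
  shared <- Reduce(intersect, detected)
  universe <- Reduce(union, detected)
  membership <- vapply(detected, function(s) universe %in% s,
                       logical(length(universe)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  region <- apply(membership, 1, function(row) paste(groups[row], collapse = "&"))
  venn <- tibble(region = region) |> count(.data$region, name = "n")
  list(shared = shared, detected = detected, venn = venn)
}

#' Screen core taxa
#'
#' Core taxa are the three-way intersection of (i) zOTUs shared across all
#' treatments, (ii) habitat specialists from the SPEC-OCCU screen and
#' (iii) network keystones from the Zi-Pi classification. Per-core mean
#' relative abundance by treatment x stage is attached when a table is
#' supplied. An empty intersection is a valid (warned) outcome.
#'
#' @param shared Character vector of shared zOTUs (or the list from
#'   [shared_taxa()]).
#' @param specialists Character vector of specialist zOTUs (or a
#'   `spec_occu_table`, in which case flagged specialists of any habitat
#'   are used).
#' @param keystones Character vector of keystone zOTUs (or a
#'   `node_role_table`).
#' @param table Optional [count_table()] for per-treatment x stage mean
#'   relative abundances of the core taxa.
#' @return A `core_taxa_result`: list with `core` (character vector),
#'   the three input sets, and `abundance` (tibble, or `NULL`).
#' @export
core_taxa <- function(shared, specialists, keystones, table = NULL) {
  if (is.list(shared) && !is.data.frame(shared)) shared <- shared$shared
  if (inherits(specialists, "spec_occu_table")) {
    specialists <- unique(specialists$zotu_id[specialists$specialist])
  }
  if (inherits(keystones, "node_role_table")) {
    keystones <- keystones$node[keystones$keystone]
  }
  core <- Reduce(intersect, list(shared, specialists, keystones))
  if (length(core) == 0) warn("core_taxa: the three-way intersection is empty.")
  abundance <- NULL
  if (!is.null(table) && length(core) > 0) {
    rel <- relative_abundance(table)
    abundance <- as_tibble(rel[core, , drop = FALSE], rownames = "zotu_id") |>
      pivot_longer(-"zotu_id", names_to = "sample_id", values_to = "rel_abund") |>
      left_join(table$sample_meta, by = "sample_id") |>
      group_by(.data$zotu_id, .data$treatment, .data$stage) |>
      summarise(mean_rel_abund = mean(.data$rel_abund), .groups = "drop")
  }
  structure(list(core = core, shared = shared, specialists = specialists,
                 keystones = keystones, abundance = abundance),
            class = "core_taxa_result")
}

#' @export
print.core_taxa_result <- function(x, ...) {
  cat(sprintf("<core_taxa_result> %d core taxa (shared %d, specialists %d, keystones %d)\n",
              length(x$core), length(x$shared), length(x$specialists),
              length(x$keystones)))
  if (length(x$core) > 0) cat("  core:", paste(x$core, collapse = ", "), "\n")
  invisible(x)
}

#' Correlate taxon abundance with a stability index
#'
#' Pearson correlation (two-sided p) between each taxon's per-sample
#' relative abundance and a per-sample stability value (e.g. the absolute
#' negative cohesion), pairs aligned by sample id. Zero variance in
#' either vector gives `NA` (flagged).
#'
#' @param abund Taxa x sample relative-abundance matrix (rows = the taxa
#'   to test, e.g. core taxa).
#' @param stability A tibble with `sample_id` and one numeric column (or a
#'   named numeric vector keyed by sample id).
#' @return A tibble `zotu_id`, `r`, `p`, `n`.
#' @export
abundance_stability_correlation <- function(abund, stability) {
  abund <- unclass(as.matrix(abund))
  if (is.data.frame(stability)) {
    value_col <- setdiff(names(stability), "sample_id")[1]
    stability <- stats::setNames(stability[[value_col]], stability$sample_id)
  }
  common <- intersect(colnames(abund), names(stability))
  if (length(common) < 4) abort("need at least 4 paired observations.")
  y <- stability[common]
  purrr::map_dfr(rownames(abund), function(id) {
    x <- abund[id, common]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      inform(sprintf("abundance_stability_correlation: zero variance for '%s'; correlation undefined.", id))
      return(tibble(zotu_id = id, r = NA_real_, p = NA_real_, n = length(common)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble(zotu_id = id, r = unname(ct$estimate), p = ct$p.value, n = length(common))
  })
}
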