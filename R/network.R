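#' Spearman correlation matrix with p-values
#'
#' Rank correlation (average ranks for ties) between all taxon pairs across
#' samples, with two-sided p-values from the t-distribution approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom. For
#' small sample counts an exact permutation p-value is available
#' (`exact = TRUE`, n <= 10; full enumeration up to n = 8, otherwise it
#' errors — 10! permutations are enumerable but rarely worth the cost).
#' Constant (zero-variance) taxa yield `NA` correlations, which are never
#' promoted to edges downstream.
#'
#' @param abund Numeric matrix, taxa x samples (e.g. a
#'   [relative_abundance()] matrix).
#' @param exact Use exact permutation p-values (n <= 8).
#' @return A list with symmetric matrices `rho` (unit diagonal) and `p`.
#' @export
spearman_matrix <- function(abund, exact = FALSE) {
  abund <- unclass(as.matrix(abund))
  n <- ncol(abund)
  if (n < 4) abort("need at least 4 samples for Spearman correlation.")
  ranks <- t(apply(abund, 1, rank)) # average ranks for ties
  constant <- apply(abund, 1, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(t(ranks), method = "pearson"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  if (exact) {
    if (n > 10) abort("exact permutation p-values are limited to n <= 10 samples.")
    if (n > 8) abort("exact enumeration implemented up to n = 8 samples (8! = 40,320 permutations).")
    p <- exact_spearman_p(rho, n)
  } else {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[!is.finite(rho)] <- NA_real_
  }
  diag(p) <- NA_real_
  list(rho = rho, p = p)
}

# Null distribution of Spearman rho under full enumeration of sample
# permutations (distinct rank orders of one margin suffice).
exact_spearman_p <- function(rho, n) {
  perms <- permutations_of(n)
  base <- seq_len(n)
  null_rho <- apply(perms, 1, function(pr) suppressWarnings(stats::cor(base, pr)))
  p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- rho[idx[k, 1], idx[k, 2]]
    if (is.finite(r)) {
      pv <- mean(abs(null_rho) >= abs(r) - 1e-12)
      p[idx[k, 1], idx[k, 2]] <- p[idx[k, 2], idx[k, 1]] <- pv
    }
  }
  p
}

# Monte-Carlo permutation refinement of extreme Spearman p-values.
#
# The t-approximation is adequate in the bulk but anti-conservative in the
# far tail, and badly so for heavily tied (sparse-count) vectors; with
# thousands of pairs tested per network, that tail error alone manufactures
# spurious |rho| > 0.8 edges. For pairs whose approximate p falls below
# `cutoff`, the p-value is re-estimated against the exact conditional null
# given both vectors' tie patterns (random re-pairing of the two rank
# multisets), Monte-Carlo approximated with `B` draws, and the final p is
# the more conservative of the two. Rank vectors are canonicalised
# (sorted) first, so the refined p is invariant to sample order, and the
# null sample is cached per tie-pattern pair.
refine_spearman_p <- function(ranks, rho, p, cutoff = 1e-3, B = 1000000L,
                              seed = 1L) {
  need <- which(upper.tri(p) & is.finite(p) & p < cutoff, arr.ind = TRUE)
  if (nrow(need) == 0) return(p)
  n <- ncol(ranks)
  perms <- cached_perms(n, B, seed) # n x B
  # sorted |null| samples are cached across calls per tie-pattern pair
  # (the no-ties pattern dominates, so most pairs share one sample), and
  # each candidate's exceedance count is a binary search
  null_for <- function(rx, ry) {
    key <- paste("null", n, B, seed, paste(rx, collapse = ","),
                 paste(ry, collapse = ","), sep = "|")
    got <- get0(key, envir = .perm_cache)
    if (!is.null(got)) return(got)
    mx <- mean(rx); my <- mean(ry)
    denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    val <- numeric(B)
    chunk <- 100000L
    for (start in seq(1L, B, by = chunk)) { # bounded allocations
      idx <- start:min(start + chunk - 1L, B)
      ry_perm <- matrix(ry[perms[, idx]], n)
      val[idx] <- (as.numeric(crossprod(rx, ry_perm)) - n * mx * my) / denom
    }
    val <- sort.int(abs(val))
    if (length(ls(.perm_cache)) > 40) {
      drop <- grep("^null", ls(.perm_cache), value = TRUE)[1]
      if (!is.na(drop)) rm(list = drop, envir = .perm_cache)
    }
    assign(key, val, envir = .perm_cache)
    val
  }
  for (k in seq_len(nrow(need))) {
    i <- need[k, 1]; j <- need[k, 2]
    nr_abs <- null_for(sort(ranks[i, ]), sort(ranks[j, ]))
    exceed <- B - findInterval(abs(rho[i, j]) - 1e-12, nr_abs)
    # conservative Monte-Carlo p: Poisson-rate upper 99.9% bound on the
    # exceedance count, so estimation noise cannot push a borderline
    # pair under the BH bar
    p_perm <- stats::qgamma(0.999, exceed + 1) / B
    p[i, j] <- p[j, i] <- max(p[i, j], min(1, p_perm))
  }
  p
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`), capped
#' at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA`s pass through).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Build a signed co-occurrence network
#'
#' The network-construction rule applied throughout the pipeline: restrict
#' the table to one analysis dataset (one compartment x treatment, stages
#' and replicates pooled), drop zOTUs at or below `min_rel_abund` mean
#' relative abundance, compute Spearman correlations on relative
#' abundances, BH-adjust the p-values over every pair actually tested
#' within the network, and keep edges with `|rho| > rho_threshold` and
#' `p_fdr < alpha`. Nodes are the retained zOTUs participating in at least
#' one edge (isolated nodes are excluded from node counts and reported).
#'
#' @param table A [count_table()] holding one dataset's samples.
#' @param rho_threshold Absolute Spearman threshold (default 0.8).
#' @param alpha FDR level (default 0.05).
#' @param min_rel_abund Mean within-kingdom relative-abundance screen
#'   (default 1e-4, i.e. 0.01%).
#' @param min_occupancy Minimum fraction of the dataset's samples in which
#'   a zOTU must be present (count > 0) to enter the correlation step
#'   (default 0.9, i.e. at most one absence out of 15 samples). Sparse
#'   taxa yield heavily tied, quasi-binary rank vectors whose Spearman
#'   null distribution has far heavier tails than the t-approximation
#'   assumes, so without this screen chance co-absence patterns
#'   masquerade as strong edges.
#' @param dataset Label for the network (default built from the table's
#'   compartment/treatment metadata).
#' @param exact Exact permutation p-values (see [spearman_matrix()]).
#' @param perm_refine Refine extreme p-values against a Monte-Carlo
#'   permutation null conditioned on each pair's tie patterns (default
#'   `TRUE`). The t-approximation is anti-conservative in the far tail —
#'   severely so for sparse, tie-heavy count vectors — and with
#'   thousands of pairs tested that error alone manufactures spurious
#'   edges; the refined p is `max` of the two, so BH keeps its
#'   false-discovery control.
#' @param perm_B Permutation draws for the refinement (default 1,000,000;
#'   the resolution floor `1/(B+1)` must sit well below `alpha * k / m`
#'   for a network with `k` true edges among `m` tested pairs).
#' @param seed Integer seed for the permutation refinement.
#' @return A `cooccurrence_network`: list with tibbles `nodes`
#'   (`node`, `kingdom`), `edges` (`from`, `to`, `rho`, `p_raw`, `p_fdr`,
#'   `sign`), the `dataset` label and the construction `params`.
#' @export
build_network <- function(table, rho_threshold = 0.8, alpha = 0.05,
                          min_rel_abund = 1e-4, min_occupancy = 0.9,
                          dataset = NULL, exact = FALSE,
                          perm_refine = TRUE, perm_B = 1000000L, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$counts) < 4) {
    abort("network construction needs at least 4 samples in the dataset.")
  }
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (!is.numeric(rho_threshold) || length(rho_threshold) != 1L) {
    abort("`rho_threshold` must be a single number.")
  }
  dataset <- dataset %||% paste(
    unique(table$sample_meta$compartment) %||% "all",
    paste(unique(table$sample_meta$treatment), collapse = "+"), sep = "_")

  # screens and correlations operate on within-kingdom relative
  # abundances: each kingdom is its own sequencing library, and pooling
  # them would let the kingdoms' independent depth fluctuations act as a
  # shared factor inflating every within-kingdom correlation
  rel_k <- kingdom_relative_abundance(table)
  keep_ab <- rowMeans(rel_k) > min_rel_abund
  if (!any(keep_ab)) {
    abort(sprintf("no zOTU exceeds mean within-kingdom relative abundance %g.",
                  min_rel_abund))
  }
  inform(sprintf(
    "build_network[%s]: retained %d / %d zOTUs (mean within-kingdom rel. abund > %g)",
    dataset, sum(keep_ab), nrow(rel_k), min_rel_abund))
  keep_taxa <- rownames(table$counts)[keep_ab]
  occ <- rowMeans(table$counts[keep_taxa, , drop = FALSE] > 0)
  names(occ) <- keep_taxa
  if (any(occ < min_occupancy)) {
    inform(sprintf(
      "build_network[%s]: %d zOTU(s) below %.0f%% occupancy excluded from correlation testing",
      dataset, sum(occ < min_occupancy), 100 * min_occupancy))
    keep_taxa <- keep_taxa[occ >= min_occupancy]
  }
  # relative abundances keep the FULL kingdom totals as denominators:
  # renormalising over the retained taxa alone would be a closure over a
  # handful of (often mutually correlated) taxa and distort their ranks
  rel <- rel_k[keep_taxa, , drop = FALSE]
  filtered <- subset_count_table(table, taxa = keep_taxa)
  sp <- spearman_matrix(rel, exact = exact)
  if (perm_refine && !exact) {
    ranks <- t(apply(unclass(rel), 1, rank))
    sp$p <- refine_spearman_p(ranks, sp$rho, sp$p, B = perm_B,
                              seed = derive_seed(seed, 7L))
  }

  ut <- upper.tri(sp$rho)
  tested <- ut & is.finite(sp$rho)
  p_fdr <- matrix(NA_real_, nrow(sp$p), ncol(sp$p))
  p_fdr[tested] <- fdr_adjust(sp$p[tested])
  keep <- tested & abs(sp$rho) > rho_threshold & p_fdr < alpha
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(rel)
  edges <- tibble(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    rho = sp$rho[keep], p_raw = sp$p[keep], p_fdr = p_fdr[keep]) |>
    mutate(sign = ifelse(.data$rho > 0, "positive", "negative")) |>
    arrange(.data$from, .data$to)

  member <- sort(unique(c(edges$from, edges$to)))
  isolated <- setdiff(ids, member)
  inform(sprintf(
    "build_network[%s]: %d edges over %d nodes (%d retained zOTUs had no significant edge and are excluded)",
    dataset, nrow(edges), length(member), length(isolated)))
  nodes <- filtered$taxon_meta |>
    filter(.data$zotu_id %in% member) |>
    transmute(node = .data$zotu_id, kingdom = .data$kingdom)

  structure(
    list(nodes = nodes, edges = edges, dataset = dataset,
         params = list(rho_threshold = rho_threshold, alpha = alpha,
                       min_rel_abund = min_rel_abund,
                       min_occupancy = min_occupancy,
                       n_samples = ncol(table$counts),
                       n_tested_taxa = nrow(rel),
                       isolated = isolated)),
    class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network '%s'> %d nodes, %d edges (%d positive / %d negative)\n",
              x$dataset, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Node attribute `kingdom` and edge attributes `rho`/`sign` are carried
#' over; the graph is undirected and simple.
#'
#' @param net A `cooccurrence_network`.
#' @return An `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "rho", "sign")],
    directed = FALSE, vertices = net$nodes)
}

#' Summarise edges by kingdom membership
#'
#' Counts intra-kingdom edges per kingdom and inter-kingdom edges per
#' unordered kingdom pair, plus node counts per kingdom; intra + inter
#' totals equal the edge count.
#'
#' @param net A `cooccurrence_network`.
#' @return A list of tibbles `edges` (`kingdom_pair`, `type`, `n`) and
#'   `nodes` (`kingdom`, `n`).
#' @export
edge_kingdom_summary <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  kof <- stats::setNames(net$nodes$kingdom, net$nodes$node)
  if (anyNA(kof[c(net$edges$from, net$edges$to)])) {
    abort("every node needs a kingdom label.")
  }
  k1 <- kof[net$edges$from]; k2 <- kof[net$edges$to]
  pair <- paste(pmin(k1, k2), pmax(k1, k2), sep = "-")
  edges <- tibble(kingdom_pair = pair, type = ifelse(k1 == k2, "intra", "inter")) |>
    count(.data$kingdom_pair, .data$type, name = "n")
  nodes <- net$nodes |> count(.data$kingdom, name = "n")
  list(edges = edges, nodes = nodes)
}

#' Count positive and negative edges
#'
#' @param net A `cooccurrence_network`.
#' @return A one-row tibble `n_positive`, `n_negative`; they sum to the
#'   edge count.
#' @export
edge_sign_summary <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  tibble(n_positive = sum(net$edges$sign == "positive"),
         n_negative = sum(net$edges$sign == "negative"))
}

#' Write / read a network edge list
#'
#' Edge-list TSV (`source`, `target`, `rho`, `p_raw`, `p_fdr`, `sign`) plus
#' a node TSV carrying kingdom labels; `write_network` also emits GraphML
#' (kingdom as node attribute) when `graphml` is given. The TSV pair
#' round-trips through `read_network`.
#'
#' @param net A `cooccurrence_network`.
#' @param edges_file,nodes_file TSV paths.
#' @param graphml Optional GraphML output path.
#' @param dataset Dataset label to stamp on a read network.
#' @return `write_network`: the network, invisibly. `read_network`: a
#'   `cooccurrence_network`.
#' @export
write_network <- function(net, edges_file, nodes_file, graphml = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  out <- net$edges |> rename(source = "from", target = "to")
  readr::write_tsv(out, edges_file)
  readr::write_tsv(net$nodes, nodes_file)
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  }
  invisible(net)
}

#' @rdname write_network
#' @export
read_network <- function(edges_file, nodes_file, dataset = "network") {
  edges <- readr::read_tsv(edges_file, show_col_types = FALSE) |>
    rename(from = "source", to = "target")
  nodes <- readr::read_tsv(nodes_file, show_col_types = FALSE)
  structure(list(nodes = nodes, edges = edges, dataset = dataset,
                 params = list()),
            class = "cooccurrence_network")
}
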