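#' Natural connectivity of a network
#'
#' The log of the average exponentiated eigenvalue of the unweighted
#' symmetric adjacency matrix, `ln((1/N) sum_i exp(lambda_i))`. It measures
#' the weighted density of closed walks and hence the redundancy of
#' alternative paths — the structural-robustness quantity tracked under
#' node removal. Computed with an overflow-safe log-sum-exp, so large
#' dense graphs do not overflow `exp`. An edgeless graph (all eigenvalues
#' zero) scores exactly 0.
#'
#' @param net A `cooccurrence_network`, an `igraph` graph, or a square
#'   symmetric 0/1 adjacency matrix.
#' @return The natural connectivity (scalar).
#' @export
natural_connectivity <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 1) abort("need at least one node.")
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(lambda)
}

as_adjacency <- function(net) {
  if (inherits(net, "cooccurrence_network")) net <- as_igraph(net)
  if (inherits(net, "igraph")) {
    a <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
    a[a > 0] <- 1
    return(a)
  }
  a <- unclass(as.matrix(net))
  if (nrow(a) != ncol(a) || any(a != t(a))) abort("adjacency must be square and symmetric.")
  a[a != 0] <- 1
  diag(a) <- 0
  a
}

#' Robustness under random node removal
#'
#' For each removal fraction, deletes that share of nodes uniformly at
#' random (induced subgraph on the survivors) and records the natural
#' connectivity and average degree of what remains; repeated `n_rep` times
#' per fraction. The decline of natural connectivity with removal fraction
#' is the robustness readout; average degree is tracked in parallel.
#'
#' @param net A `cooccurrence_network` or `igraph` graph with >= 2 nodes.
#' @param fractions Removal fractions in `[0, 1)` (default 0 to 0.8 by
#'   0.05).
#' @param n_rep Repetitions per fraction (default 100).
#' @param seed Integer seed.
#' @return A `robustness_curve`: tibble with `fraction`, `n_removed`,
#'   `mean_nc`, `sd_nc`, `mean_avg_degree`, `sd_avg_degree`, `n_rep`. The
#'   fraction-0 row equals the intact network exactly (sd 0).
#' @export
robustness_curve <- function(net, fractions = seq(0, 0.8, by = 0.05),
                             n_rep = 100, seed = 1L) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  n <- igraph::vcount(g)
  if (n < 2) abort("robustness needs at least 2 nodes.")
  if (any(fractions < 0 | fractions >= 1)) abort("removal fractions must lie in [0, 1).")
  a <- as_adjacency(g)
  out <- with_seed(seed, {
    purrr::map_dfr(fractions, function(f) {
      n_rm <- round(f * n)
      if (n_rm == 0) {
        nc <- log_mean_exp(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
        return(tibble(fraction = f, n_removed = 0L,
                      mean_nc = nc, sd_nc = 0,
                      mean_avg_degree = sum(a) / n, sd_avg_degree = 0))
      }
      reps <- vapply(seq_len(n_rep), function(r) {
        keep <- sort(sample.int(n, n - n_rm))
        sub <- a[keep, keep, drop = FALSE]
        c(log_mean_exp(eigen(sub, symmetric = TRUE, only.values = TRUE)$values),
          sum(sub) / length(keep))
      }, numeric(2))
      tibble(fraction = f, n_removed = n_rm,
             mean_nc = mean(reps[1, ]), sd_nc = stats::sd(reps[1, ]),
             mean_avg_degree = mean(reps[2, ]), sd_avg_degree = stats::sd(reps[2, ]))
    })
  })
  out$n_rep <- as.integer(n_rep)
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Per-taxon positive and negative connectedness
#'
#' For each network taxon, the average of its significant positive edge
#' correlations (0 if none) and the average of its significant negative
#' edge correlations (0 if none). The mean (rather than sum) follows the
#' cohesion method's source; `method = "sum"` switches to the summed
#' correlations.
#'
#' @param net A `cooccurrence_network`.
#' @param method `"mean"` (default) or `"sum"`.
#' @return A tibble `node`, `pos_connectedness` (>= 0),
#'   `neg_connectedness` (<= 0).
#' @export
connectedness <- function(net, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "cooccurrence_network"))
  agg <- if (method == "mean") mean else sum
  long <- bind_rows(
    net$edges |> select(node = "from", rho = "rho"),
    net$edges |> select(node = "to", rho = "rho"))
  per <- long |>
    group_by(.data$node) |>
    summarise(
      pos_connectedness = if (any(.data$rho > 0)) agg(.data$rho[.data$rho > 0]) else 0,
      neg_connectedness = if (any(.data$rho < 0)) agg(.data$rho[.data$rho < 0]) else 0,
      .groups = "drop")
  net$nodes |>
    select(node = "node") |>
    left_join(per, by = "node") |>
    mutate(pos_connectedness = coalesce(.data$pos_connectedness, 0),
           neg_connectedness = coalesce(.data$neg_connectedness, 0))
}

#' Per-sample community cohesion
#'
#' Cohesion of sample `s` is the abundance-weighted sum of taxon
#' connectedness over the whole community: `sum_i a_is * c_i`, computed
#' separately for positive and negative connectedness, with `a_is` the
#' taxon's relative abundance in the full community and `c_i = 0` for
#' taxa without significant correlations. Weighting by community-wide
#' abundance means cohesion reflects how much of the community is wired
#' into the network: a sample dominated by unconnected taxa scores low
#' even if its few network members are strongly correlated.
#' `renormalise = TRUE` instead rescales abundances over the network's
#' taxa within each sample (`sum a_i = 1`), which makes cohesion a pure
#' mean-connectedness measure, comparable across networks of different
#' size but blind to wiring density. Total cohesion is
#' `positive + |negative|`; the `|negative|/positive` ratio is `NA` when
#' positive cohesion is 0.
#'
#' @param abund A [relative_abundance()] matrix (or any taxa x sample
#'   abundance matrix) covering the network taxa.
#' @param conn A tibble from [connectedness()] (or a `cooccurrence_network`,
#'   in which case connectedness is computed with defaults).
#' @param renormalise Rescale abundances over network taxa per sample
#'   (default `FALSE`: community-wide weighting).
#' @return A `cohesion_result` tibble: `sample_id`, `pos_cohesion` (>= 0),
#'   `neg_cohesion` (<= 0), `total_cohesion`, `neg_pos_ratio`.
#' @export
cohesion <- function(abund, conn, renormalise = FALSE) {
  if (inherits(conn, "cooccurrence_network")) conn <- connectedness(conn)
  abund <- unclass(as.matrix(abund))
  missing <- setdiff(conn$node, rownames(abund))
  if (length(missing) > 0) {
    abort(paste0("abundance matrix lacks network taxa: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  sub <- abund[conn$node, , drop = FALSE]
  tot <- colSums(sub)
  zero <- tot == 0
  if (any(zero)) {
    inform(paste0("cohesion: sample(s) with zero abundance on network taxa: ",
                  paste(colnames(sub)[zero], collapse = ", ")))
  }
  a <- if (renormalise) {
    sweep(sub, 2, ifelse(zero, 1, tot), "/")
  } else {
    sub
  }
  pos <- as.numeric(crossprod(a, conn$pos_connectedness))
  neg <- as.numeric(crossprod(a, conn$neg_connectedness))
  out <- tibble(sample_id = colnames(sub),
                pos_cohesion = pos, neg_cohesion = neg,
                total_cohesion = pos + abs(neg),
                neg_pos_ratio = ifelse(pos > 0, abs(neg) / pos, NA_real_))
  class(out) <- c("cohesion_result", class(out))
  out
}

#' Average variation degree (AVD) of a replicate group
#'
#' For each zOTU `i` and replicate sample `k` of one group,
#' `a_ik = |x_ik - mean_i| / sd_i` (sd over the group's replicates, n-1
#' denominator); `AVD = sum_ik a_ik / (k * n)` over the `k` replicates and
#' all `n` zOTUs. zOTUs with zero sd (including all-absent ones)
#' contribute 0. Higher AVD means larger standardised replicate-to-replicate
#' fluctuation, i.e. lower community stability.
#'
#' @param abund Taxa x sample abundance matrix (relative abundances).
#' @param samples Sample ids of one replicate group (>= 2), e.g. all
#'   replicates of one treatment pooled across stages.
#' @return The AVD value (scalar >= 0).
#' @export
avd <- function(abund, samples = colnames(abund)) {
  abund <- unclass(as.matrix(abund))
  bad <- setdiff(samples, colnames(abund))
  if (length(bad) > 0) abort(paste0("unknown samples: ", paste(bad, collapse = ", ")))
  x <- abund[, samples, drop = FALSE]
  k <- ncol(x)
  if (k < 2) abort("AVD needs at least 2 replicate samples.")
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  dev <- abs(x - mu) / ifelse(s > 0, s, Inf) # sd = 0 rows contribute 0
  sum(dev) / (k * nrow(x))
}

#' Network vulnerability
#'
#' Global efficiency is `E = (1/(N(N-1))) sum_{u != v} 1/d(u,v)` with
#' unreachable pairs contributing 0. Removing node `i` leaves the induced
#' subgraph with efficiency `E_i` (normalised over its own `N-1` nodes);
#' the node's vulnerability is `V_i = (E - E_i)/E` and the network's
#' vulnerability is `V = max_i V_i` — the worst single-node loss of
#' efficiency. `V <= 1` always; removing a peripheral node can give a
#' negative `V_i`.
#'
#' @param net A `cooccurrence_network` or `igraph` graph with >= 3 nodes
#'   and at least one edge.
#' @return A list: `vulnerability` (scalar `V`), `efficiency` (`E`), and
#'   `nodes`, a tibble of per-node `efficiency_removed` and
#'   `vulnerability`.
#' @export
vulnerability <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  n <- igraph::vcount(g)
  if (n < 3) abort("vulnerability needs at least 3 nodes.")
  eff <- function(gr) {
    m <- igraph::vcount(gr)
    if (m < 2) return(0)
    d <- igraph::distances(gr)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    2 * sum(inv) / (m * (m - 1))
  }
  e0 <- eff(g)
  if (e0 == 0) abort("global efficiency is 0 (edgeless graph); vulnerability undefined.")
  ei <- vapply(seq_len(n), function(i) eff(igraph::delete_vertices(g, i)), numeric(1))
  vi <- (e0 - ei) / e0
  nodes <- tibble(node = igraph::V(g)$name %||% as.character(seq_len(n)),
                  efficiency_removed = ei, vulnerability = vi)
  list(vulnerability = max(vi), efficiency = e0, nodes = nodes)
}

#' Full stability report for one network and its abundance table
#'
#' Bundles the stability battery: natural connectivity, the robustness
#' curve under random node removal, per-sample cohesion, AVD per replicate
#' group (the table's treatments, stages and replicates pooled per
#' treatment) and vulnerability.
#'
#' @param net A `cooccurrence_network`.
#' @param table The [count_table()] the network was built from (same
#'   dataset).
#' @param fractions,n_rep Robustness grid and repetitions (see
#'   [robustness_curve()]).
#' @param seed Integer seed.
#' @return A `stability_report`: list with `summary` (one-row tibble:
#'   natural connectivity, AVD, vulnerability, mean cohesion values),
#'   `robustness`, `cohesion`, `vulnerability_nodes`.
#' @export
stability_report <- function(net, table, fractions = seq(0, 0.8, by = 0.05),
                             n_rep = 100, seed = 1L) {
  stopifnot(inherits(net, "cooccurrence_network"), inherits(table, "count_table"))
  rel <- relative_abundance(table)
  nc <- natural_connectivity(net)
  rob <- robustness_curve(net, fractions = fractions, n_rep = n_rep, seed = seed)
  coh <- cohesion(rel, connectedness(net))
  avd_val <- avd(rel)
  vul <- if (nrow(net$nodes) >= 3) vulnerability(net) else NULL
  summary <- tibble(
    dataset = net$dataset,
    natural_connectivity = nc,
    avd = avd_val,
    vulnerability = vul$vulnerability %||% NA_real_,
    mean_pos_cohesion = mean(coh$pos_cohesion),
    mean_neg_cohesion = mean(coh$neg_cohesion),
    mean_total_cohesion = mean(coh$total_cohesion),
    mean_neg_pos_ratio = mean(coh$neg_pos_ratio, na.rm = TRUE))
  structure(list(summary = summary, robustness = rob, cohesion = coh,
                 vulnerability_nodes = vul$nodes %||% NULL),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  print(x$summary)
  invisible(x)
}
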