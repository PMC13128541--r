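#' Per-node degree and closeness centrality
#'
#' Degree is the unweighted edge count incident on each node. Closeness
#' uses the component-scaled (Wasserman-Faust) convention so it stays
#' meaningful in disconnected graphs: for node `v` in a component of size
#' `n_v` within a network of `N` nodes,
#' `closeness(v) = ((n_v - 1)/(N - 1)) * ((n_v - 1) / sum of distances from
#' v within its component)`; an isolated node scores 0. Values lie in
#' `[0, 1]`. Alternative conventions are selectable.
#'
#' @param net A `cooccurrence_network` or an `igraph` graph.
#' @param convention `"component-scaled"` (default) or `"within-component"`
#'   (the unscaled `(n_v - 1)/sum d`, classic closeness per component).
#' @return A tibble `node`, `degree`, `closeness`.
#' @export
degree_and_closeness <- function(net, convention = c("component-scaled",
                                                     "within-component")) {
  convention <- match.arg(convention)
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  n <- igraph::vcount(g)
  if (n < 1) abort("need at least one node.")
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  nv <- comp$csize[comp$membership]
  sums <- vapply(seq_len(n), function(i) {
    di <- d[i, comp$membership == comp$membership[i]]
    sum(di[is.finite(di)])
  }, numeric(1))
  clo <- ifelse(nv > 1, (nv - 1) / sums, 0)
  if (convention == "component-scaled" && n > 1) {
    clo <- clo * (nv - 1) / (n - 1)
  }
  tibble(node = igraph::V(g)$name %||% as.character(seq_len(n)),
         degree = unname(deg), closeness = unname(clo))
}

#' Detect modules by Louvain modularity maximisation
#'
#' Non-overlapping modules via the Louvain heuristic on the unweighted
#' graph (edge weights are kept as attributes but topology is counts-based),
#' with nodes processed in sorted-name order and the RNG fixed by `seed`
#' so the partition is deterministic.
#'
#' @param net A `cooccurrence_network` or `igraph` graph with >= 1 edge.
#' @param seed Integer seed.
#' @return A tibble `node`, `module` (integer ids); Newman-Girvan
#'   modularity `M` of the partition is attached as attribute
#'   `"modularity"`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  if (igraph::ecount(g) < 1) abort("module detection needs at least one edge (modularity is undefined on an edgeless graph).")
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name", value = nm)
  }
  g <- igraph::permute(g, match(nm, sort(nm))) # stable node order
  cl <- with_seed(seed, igraph::cluster_louvain(g, weights = NA))
  out <- tibble(node = igraph::V(g)$name,
                module = as.integer(igraph::membership(cl)))
  attr(out, "modularity") <- igraph::modularity(g, igraph::membership(cl))
  out[match(sort(nm), out$node), ] |> arrange(.data$node)
}

#' Relative modularity against a degree-preserving null
#'
#' `RM = (M_obs - mean(M_rand)) / mean(M_rand)` where `M_rand` are Louvain
#' modularities of `n_random` rewired versions of the graph
#' (Maslov-Sneppen double-edge swaps, `10 |E|` swaps each), quantifying how
#' much more modular the observed network is than expected for its degree
#' sequence. If rewiring cannot alter the graph (degree sequence with a
#' unique realisation, e.g. a star), an Erdos-Renyi null with the same
#' node and edge count is used instead and flagged.
#'
#' @param net A `cooccurrence_network` or `igraph` graph with >= 2 edges.
#' @param n_random Number of null graphs (default 100).
#' @param seed Integer seed.
#' @return A one-row tibble `modularity`, `rm`, `null_mean`, `null_sd`,
#'   `null_model` (`"rewired"` or `"erdos-renyi"`), `n_random`.
#' @export
relative_modularity <- function(net, n_random = 100, seed = 1L) {
  g <- if (inherits(net, "cooccurrence_network")) as_igraph(net) else net
  if (igraph::ecount(g) < 2) abort("relative modularity needs at least 2 edges.")
  m_obs <- attr(detect_modules(g, seed = seed), "modularity")
  edge_key <- function(gr) {
    el <- igraph::as_edgelist(gr, names = FALSE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), collapse = ";")
  }
  rewirable <- with_seed(derive_seed(seed, 99L), {
    any(vapply(1:5, function(i) {
      edge_key(igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))) != edge_key(g)
    }, logical(1)))
  })
  null_model <- if (rewirable) "rewired" else "erdos-renyi"
  if (!rewirable) {
    inform("relative_modularity: degree sequence admits no rewiring; falling back to an Erdos-Renyi null with matching n and |E|.")
  }
  m_rand <- vapply(seq_len(n_random), function(i) {
    gi <- with_seed(derive_seed(seed, i), {
      if (rewirable) {
        igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      } else {
        igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
      }
    })
    attr(detect_modules(gi, seed = derive_seed(seed, i + n_random)), "modularity")
  }, numeric(1))
  mu <- mean(m_rand)
  tibble(modularity = m_obs,
         rm = if (abs(mu) < .Machine$double.eps) NA_real_ else (m_obs - mu) / mu,
         null_mean = mu, null_sd = stats::sd(m_rand),
         null_model = null_model, n_random = as.integer(n_random))
}

#' Find network hubs by closeness and degree
#'
#' Network hubs are nodes with closeness centrality strictly above
#' `closeness_min` and degree strictly above `degree_min` (defaults 0.25
#' and 40, the conventional cut-offs for dense microbiome networks).
#'
#' @param centrality A tibble from [degree_and_closeness()], or a
#'   `cooccurrence_network` (centralities are computed on the fly).
#' @param closeness_min,degree_min Strict lower thresholds.
#' @param nodes Optional node tibble carrying kingdom labels to attach.
#' @return The hub rows of the centrality tibble (possibly empty), with
#'   kingdom labels when available.
#' @export
find_network_hubs <- function(centrality, closeness_min = 0.25, degree_min = 40,
                              nodes = NULL) {
  if (inherits(centrality, "cooccurrence_network")) {
    nodes <- nodes %||% centrality$nodes
    if (nrow(centrality$nodes) == 0) {
      return(tibble(node = character(), degree = numeric(),
                    closeness = numeric()))
    }
    centrality <- degree_and_closeness(centrality)
  }
  hubs <- centrality |>
    filter(.data$closeness > closeness_min, .data$degree > degree_min)
  if (!is.null(nodes) && "kingdom" %in% names(nodes)) {
    hubs <- hubs |> left_join(nodes, by = "node")
  }
  hubs
}

#' Network-level topology report
#'
#' Bundles the descriptors used to compare network complexity: node and
#' edge counts, average degree (`2 |E| / N`), modularity and relative
#' modularity, per-node centralities and module assignments, and the hub
#' list.
#'
#' @param net A `cooccurrence_network`.
#' @param n_random Null graphs for relative modularity.
#' @param seed Integer seed.
#' @param closeness_min,degree_min Hub thresholds (see
#'   [find_network_hubs()]).
#' @return A `topology_report`: list with `summary` (one-row tibble),
#'   `nodes` (per-node tibble: degree, closeness, module, is_hub) and
#'   `hubs`.
#' @export
network_topology <- function(net, n_random = 100, seed = 1L,
                             closeness_min = 0.25, degree_min = 40) {
  stopifnot(inherits(net, "cooccurrence_network"))
  cent <- degree_and_closeness(net)
  mods <- detect_modules(net, seed = seed)
  rm_row <- relative_modularity(net, n_random = n_random, seed = seed)
  node_tbl <- net$nodes |>
    left_join(cent, by = "node") |>
    left_join(mods, by = "node") |>
    mutate(is_hub = .data$closeness > closeness_min & .data$degree > degree_min)
  hubs <- node_tbl |> filter(.data$is_hub)
  summary <- tibble(
    dataset = net$dataset,
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    average_degree = if (nrow(net$nodes) > 0) 2 * nrow(net$edges) / nrow(net$nodes) else NA_real_,
    modularity = rm_row$modularity, relative_modularity = rm_row$rm,
    null_model = rm_row$null_model, n_modules = max(mods$module),
    n_hubs = nrow(hubs))
  structure(list(summary = summary, nodes = node_tbl, hubs = hubs),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n")
  print(x$summary)
  invisible(x)
}
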