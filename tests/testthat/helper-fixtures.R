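# Small in-code fixtures shared across tests.

toy_counts <- function(counts = NULL, samples = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 5, 0,
                       20, 0, 4,
                       30, 15, 8,
                       40, 20, 12), nrow = 4, byrow = TRUE)
  }
  rownames(counts) <- paste0("zOTU_", seq_len(nrow(counts)))
  colnames(counts) <- samples %||% paste0("s", seq_len(ncol(counts)))
  counts
}

toy_table <- function(counts = NULL, treatments = NULL, kingdoms = NULL) {
  counts <- if (is.null(counts)) toy_counts() else counts
  ns <- ncol(counts)
  sm <- tibble::tibble(
    sample_id = colnames(counts), compartment = "root",
    treatment = treatments %||% rep("CK", ns),
    stage = "tillering", replicate = seq_len(ns))
  tm <- tibble::tibble(
    zotu_id = rownames(counts),
    kingdom = kingdoms %||% rep("prokaryote", nrow(counts)),
    taxonomy = paste0("k__x; g__g", seq_len(nrow(counts))))
  count_table(counts, sm, tm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# igraph builders for topology fixtures
graph_from_pairs <- function(pairs, n = NULL, names = NULL) {
  g <- igraph::make_graph(as.character(t(pairs)), directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n) {
    extra <- setdiff(as.character(seq_len(n)), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

# wrap an igraph graph as a cooccurrence_network with all-positive rho
net_from_graph <- function(g, rho = 0.9, dataset = "test") {
  el <- igraph::as_edgelist(g)
  nodes <- tibble::tibble(node = igraph::V(g)$name %||%
                            as.character(seq_len(igraph::vcount(g))),
                          kingdom = "prokaryote")
  rho <- rep_len(rho, nrow(el))
  edges <- tibble::tibble(from = el[, 1], to = el[, 2], rho = rho,
                          p_raw = 1e-6, p_fdr = 1e-5,
                          sign = ifelse(rho > 0, "positive", "negative"))
  structure(list(nodes = nodes, edges = edges, dataset = dataset,
                 params = list()),
            class = "cooccurrence_network")
}

complete_graph <- function(n) {
  igraph::set_vertex_attr(igraph::make_full_graph(n), "name",
                          value = as.character(seq_len(n)))
}

# brute-force natural connectivity straight from the definition
nc_oracle <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  log(mean(exp(ev)))
}
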