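#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a co-occurrence network into its edge table
#'
#' @param x A `cooccurrence_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `rho`, `p_raw`, `p_fdr`,
#'   `sign`) with the dataset label attached.
#' @export
tidy.cooccurrence_network <- function(x, ...) {
  x$edges |> mutate(dataset = x$dataset)
}

#' One-row summary of a co-occurrence network
#'
#' @param x A `cooccurrence_network`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, sign split, average degree.
#' @export
glance.cooccurrence_network <- function(x, ...) {
  tibble(dataset = x$dataset,
         n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign == "positive"),
         n_negative = sum(x$edges$sign == "negative"),
         average_degree = if (nrow(x$nodes) > 0) 2 * nrow(x$edges) / nrow(x$nodes) else NA_real_)
}

#' Tidy a topology report into its per-node table
#'
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return The per-node tibble (degree, closeness, module, hub flag).
#' @export
tidy.topology_report <- function(x, ...) x$nodes

#' @export
glance.topology_report <- function(x, ...) x$summary

#' Tidy a stability report into its per-sample cohesion table
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return The cohesion tibble.
#' @export
tidy.stability_report <- function(x, ...) x$cohesion

#' @export
glance.stability_report <- function(x, ...) x$summary

#' Tidy a core-taxa result
#'
#' @param x A `core_taxa_result`.
#' @param ... Unused.
#' @return A tibble with one row per candidate zOTU and logical columns
#'   for each screen plus the core flag.
#' @export
tidy.core_taxa_result <- function(x, ...) {
  universe <- sort(unique(c(x$shared, x$specialists, x$keystones)))
  tibble(zotu_id = universe,
         shared = universe %in% x$shared,
         specialist = universe %in% x$specialists,
         keystone = universe %in% x$keystones,
         core = universe %in% x$core)
}

#' @export
glance.core_taxa_result <- function(x, ...) {
  tibble(n_shared = length(x$shared), n_specialists = length(x$specialists),
         n_keystones = length(x$keystones), n_core = length(x$core))
}
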