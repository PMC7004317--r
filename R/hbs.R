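#' Assemble the hub / bottleneck / SSG (HBS) gene set
#'
#' Groups the three gene classes driving the salt-sensitivity subnetwork —
#' degree hubs, betweenness bottlenecks and the curated salt-sensitivity
#' genes — into one union with full overlap arithmetic, the membership basis
#' of the SS-PIN.
#'
#' @param hubs,bottlenecks,ssgs Character vectors of gene symbols.
#' @return An object of class `hbs_report`: list with the three input sets
#'   (upper-cased, deduplicated), `union`, and `overlaps`, a tibble of the
#'   pairwise and triple intersection sizes. Supports [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' rep <- assemble_hbs(c("A", "B"), c("B", "C"), c("C", "D"))
#' glance(rep)
assemble_hbs <- function(hubs, bottlenecks, ssgs) {
  h <- unique(norm_symbols(hubs))
  b <- unique(norm_symbols(bottlenecks))
  s <- unique(norm_symbols(ssgs))
  hb <- intersect(h, b)
  hs <- intersect(h, s)
  bs <- intersect(b, s)
  hbs <- intersect(hb, s)
  structure(
    list(hubs = h, bottlenecks = b, ssgs = s,
         union = sort(union(union(h, b), s)),
         overlaps = tibble::tibble(
           n_hubs = length(h), n_bottlenecks = length(b), n_ssgs = length(s),
           hub_bottleneck = length(hb), hub_ssg = length(hs),
           bottleneck_ssg = length(bs), triple = length(hbs))),
    class = "hbs_report"
  )
}

#' @export
print.hbs_report <- function(x, ...) {
  o <- x$overlaps
  cat(sprintf(paste0(
    "HBS report: %d hubs, %d bottlenecks, %d SSGs -> union of %d genes\n",
    "  overlaps: hub/bottleneck %d, hub/SSG %d, bottleneck/SSG %d, triple %d\n"),
    o$n_hubs, o$n_bottlenecks, o$n_ssgs, length(x$union),
    o$hub_bottleneck, o$hub_ssg, o$bottleneck_ssg, o$triple))
  invisible(x)
}

#' Extract the salt-sensitivity protein interaction network (SS-PIN)
#'
#' The SS-PIN is the subgraph of the cleaned PIN induced on the HBS union.
#'
#' @param pin Cleaned PIN edge tibble (see [clean_network()]).
#' @param hbs An `hbs_report` from [assemble_hbs()], or a plain character
#'   vector of gene symbols.
#' @return Edge tibble of the induced subnetwork.
#' @export
extract_sspin <- function(pin, hbs) {
  keep <- if (inherits(hbs, "hbs_report")) hbs$union else norm_symbols(hbs)
  induced_subgraph(pin, keep)
}

#' Edge-to-node ratio of a network
#'
#' @param edges Cleaned edge tibble, or a single number of edges (in which
#'   case `n_nodes` must be given).
#' @param n_nodes Node count; defaults to the number of distinct endpoint
#'   symbols in `edges` (supply it explicitly when the network has isolated
#'   nodes).
#' @return `|E| / |V|` as a plain number (summaries print it to 2 decimals).
#' @export
#' @examples
#' edge_node_ratio(15474, n_nodes = 2691)
edge_node_ratio <- function(edges, n_nodes = NULL) {
  if (is.numeric(edges) && length(edges) == 1) {
    n_edges <- edges
    if (is.null(n_nodes)) abort("`n_nodes` is required when `edges` is a count.")
  } else {
    n_edges <- nrow(edges)
    n_nodes <- n_nodes %||% length(union(edges$gene_1, edges$gene_2))
  }
  if (n_nodes == 0) abort("Edge-node ratio is undefined for an empty network.")
  n_edges / n_nodes
}

#' One-row size summary of a network
#'
#' @param edges Cleaned edge tibble.
#' @param nodes Optional full node set including isolates.
#' @return Tibble with `n_nodes`, `n_edges`, `edge_node_ratio` (2 decimals).
#' @export
network_summary <- function(edges, nodes = NULL) {
  nodes <- union(norm_symbols(nodes %||% character()),
                 union(edges$gene_1, edges$gene_2))
  tibble::tibble(
    n_nodes = length(nodes), n_edges = nrow(edges),
    edge_node_ratio = round(nrow(edges) / max(length(nodes), 1L), 2))
}
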