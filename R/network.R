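#' Clean a raw interaction edge list into a simple undirected network
#'
#' Protein-interaction exports routinely carry self-loops and the same
#' interaction in both orientations. This drops self-loops, merges `(a, b)`
#' with `(b, a)`, removes duplicates and upper-cases symbols, yielding the
#' canonical edge table every other network function consumes. The operation
#' is idempotent.
#'
#' @param raw_edges Data frame whose first two columns are interaction
#'   endpoints (extra columns are ignored), or a two-column character matrix.
#' @return Tibble with columns `gene_1`, `gene_2`; each unordered pair
#'   appears once with `gene_1 < gene_2`, sorted.
#' @export
#' @examples
#' clean_network(data.frame(a = c("a", "B", "A"), b = c("B", "A", "A")))
clean_network <- function(raw_edges) {
  if (is.matrix(raw_edges)) raw_edges <- as.data.frame(raw_edges)
  if (!is.data.frame(raw_edges) || ncol(raw_edges) < 2) {
    abort("`raw_edges` must have at least two columns (the edge endpoints).")
  }
  edges <- tibble::tibble(gene_1 = norm_symbols(raw_edges[[1]]),
                          gene_2 = norm_symbols(raw_edges[[2]]))
  if (nrow(edges) == 0) {
    warn("Empty edge list; returning an empty network.")
    return(edges)
  }
  if (any(edges$gene_1 == "" | edges$gene_2 == "")) {
    abort("Edge endpoints must be non-empty symbols.")
  }
  edges <- order_pairs(edges)
  edges <- dplyr::distinct(dplyr::filter(edges, .data$gene_1 != .data$gene_2))
  dplyr::arrange(edges, .data$gene_1, .data$gene_2)
}

#' Induced subgraph on a set of genes
#'
#' Keeps the edges whose both endpoints lie in `keep`. Used to restrict the
#' interactome to DEGs and to carve the SS-PIN out of the PIN.
#'
#' @param edges Cleaned edge tibble (see [clean_network()]).
#' @param keep Character vector of gene symbols to retain.
#' @return Edge tibble of the induced subgraph.
#' @export
induced_subgraph <- function(edges, keep) {
  keep <- norm_symbols(keep)
  dplyr::filter(edges, .data$gene_1 %in% keep & .data$gene_2 %in% keep)
}

# igraph view of a cleaned edge table; isolated nodes can be supplied so that
# normalization and degree tables cover them.
as_igraph <- function(edges, nodes = NULL) {
  nodes <- union(norm_symbols(nodes %||% character()),
                 union(edges$gene_1, edges$gene_2))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Degree centrality
#'
#' `DC(v)` is the number of interaction partners of `v` in the simple graph.
#'
#' @param edges Cleaned edge tibble.
#' @param nodes Optional full node set (isolated nodes get degree 0).
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0 && is.null(nodes)) {
    return(setNames(integer(), character()))
  }
  g <- as_igraph(edges, nodes)
  deg <- igraph::degree(g)
  setNames(as.integer(deg), names(deg))
}

#' Normalized betweenness centrality
#'
#' `BC(v)` sums, over all unordered node pairs `s != v != t`, the fraction of
#' shortest `s`-`t` paths passing through `v`, divided by the number of pairs
#' `(n - 1)(n - 2) / 2`, so values lie in `[0, 1]`. Pairs in different
#' components contribute 0; for disconnected graphs the per-component sums
#' are still normalized by the global pair count. Computed by igraph's
#' Brandes single-source accumulation; the test suite verifies it against an
#' exhaustive shortest-path enumeration oracle.
#'
#' @param edges Cleaned edge tibble.
#' @param nodes Optional full node set.
#' @return Named numeric vector of betweenness values in `[0, 1]`.
#' @export
betweenness_centrality <- function(edges, nodes = NULL) {
  if (nrow(edges) == 0 && is.null(nodes)) {
    return(setNames(numeric(), character()))
  }
  g <- as_igraph(edges, nodes)
  n <- igraph::vcount(g)
  if (n < 3) {
    warn("Betweenness needs at least 3 nodes; returning all zeros.")
    return(setNames(rep(0, n), igraph::V(g)$name))
  }
  bc <- igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  setNames(as.numeric(bc), igraph::V(g)$name)
}

#' Per-gene centrality table
#'
#' @param edges Cleaned edge tibble.
#' @param nodes Optional full node set (isolates get `dc = 0`, `bc = 0`).
#' @return Tibble with columns `gene`, `dc`, `bc`, sorted by decreasing `dc`.
#' @export
#' @examples
#' net <- clean_network(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
#' centrality_table(net)
centrality_table <- function(edges, nodes = NULL) {
  dc <- degree_centrality(edges, nodes)
  bc <- betweenness_centrality(edges, nodes)
  bc_aligned <- unname(bc[names(dc)])
  tibble::tibble(gene = names(dc), dc = unname(dc), bc = bc_aligned) |>
    dplyr::arrange(dplyr::desc(.data$dc), .data$gene)
}

#' Call hubs by the mean + k * SD degree cutoff
#'
#' The cutoff is `mean(DC) + multiplier * SD(DC)` over all nodes of the
#' analyzed network (default multiplier 2); hubs are the nodes whose degree
#' strictly exceeds it. Strict inequality keeps the call empty when all
#' degrees are equal (sd = 0). The SD is the sample SD by default;
#' `sd_mode = "population"` divides by `n` instead of `n - 1`.
#'
#' @param dc Named degree vector from [degree_centrality()], or a
#'   [centrality_table()] tibble.
#' @param multiplier Number of SDs above the mean (default 2).
#' @param sd_mode `"sample"` (default) or `"population"`.
#' @return An object of class `hub_call`: list with `hubs` (character),
#'   and `cutoff` (tibble with `avg_dc`, `sd_dc`, `multiplier`, `cutoff`).
#'   Supports [tidy()] and [glance()].
#' @export
classify_hubs <- function(dc, multiplier = 2, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  check_number(multiplier, "multiplier", min = 0)
  if (is.data.frame(dc)) dc <- setNames(dc$dc, dc$gene)
  if (length(dc) == 0) abort("`dc` must be a non-empty degree map.")
  avg <- mean(dc)
  if (length(dc) == 1) {
    warn("Single-node network: SD of degree undefined, treated as 0.")
    s <- 0
  } else {
    s <- sd(dc)
    if (sd_mode == "population") s <- s * sqrt((length(dc) - 1) / length(dc))
  }
  cutoff <- avg + multiplier * s
  structure(
    list(hubs = sort(names(dc)[dc > cutoff]),
         dc = dc,
         cutoff = tibble::tibble(avg_dc = avg, sd_dc = s,
                                 multiplier = multiplier, cutoff = cutoff)),
    class = "hub_call"
  )
}

#' @export
print.hub_call <- function(x, ...) {
  cat(sprintf("Hub call: %d hub(s) with DC > %.3f (mean %.3f + %g x SD %.3f)\n",
              length(x$hubs), x$cutoff$cutoff, x$cutoff$avg_dc,
              x$cutoff$multiplier, x$cutoff$sd_dc))
  if (length(x$hubs)) cat(" ", paste(head(x$hubs, 20), collapse = ", "),
                          if (length(x$hubs) > 20) "..." else "", "\n")
  invisible(x)
}

#' Call bottlenecks as the top quantile of the betweenness distribution
#'
#' Nodes are ranked by betweenness descending; the first
#' `ceiling(quantile * n)` are taken, extended to include any node tied with
#' the last included value so the call is deterministic and independent of
#' input order. If every betweenness is zero there are no meaningful
#' bottlenecks and the call is empty.
#'
#' @param bc Named betweenness vector from [betweenness_centrality()], or a
#'   [centrality_table()] tibble.
#' @param quantile Fraction of nodes to take from the top (default 0.25).
#' @return Character vector of bottleneck gene symbols (sorted).
#' @export
classify_bottlenecks <- function(bc, quantile = 0.25) {
  check_probability(quantile, "quantile")
  if (is.data.frame(bc)) bc <- setNames(bc$bc, bc$gene)
  if (length(bc) == 0) abort("`bc` must be a non-empty betweenness map.")
  if (all(bc == 0)) {
    warn("All betweenness values are zero; no bottlenecks called.")
    return(character())
  }
  k <- ceiling(quantile * length(bc))
  if (k == 0) return(character())
  ord <- order(-bc, names(bc))
  boundary <- bc[ord[k]]
  # Tie extension at the boundary keeps the call order-independent; nodes
  # with zero betweenness are never bottlenecks regardless of the quantile.
  sort(names(bc)[bc >= boundary & bc > 0])
}
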