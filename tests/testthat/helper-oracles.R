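# Independent oracles used to verify the implementation paths.

# Normalized betweenness by explicit enumeration of every shortest path
# between every node pair. Deliberately naive (exponential in the worst
# case); only for graphs of a dozen nodes or so.
oracle_betweenness <- function(edges, nodes) {
  nodes <- sort(nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    union(edges$gene_2[edges$gene_1 == v], edges$gene_1[edges$gene_2 == v])
  })
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    d
  }
  # All shortest s-t paths: walk from s, only stepping to neighbours one
  # unit closer to t.
  all_shortest_paths_st <- function(s, t, dist_to_t) {
    if (is.infinite(dist_to_t[s])) return(list())
    extend <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      nexts <- adj[[v]][dist_to_t[adj[[v]]] == dist_to_t[v] - 1]
      unlist(lapply(nexts, function(w) extend(c(path, w))), recursive = FALSE)
    }
    extend(s)
  }
  n <- length(nodes)
  bc <- stats::setNames(rep(0, n), nodes)
  if (n < 3) return(bc)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      dist_t <- bfs_dist(nodes[j])
      paths <- all_shortest_paths_st(nodes[i], nodes[j], dist_t)
      if (!length(paths)) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        tab <- table(interior)
        bc[names(tab)] <- bc[names(tab)] + as.numeric(tab) / length(paths)
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Random simple graph on n nodes, edge probability p.
random_graph <- function(n, p) {
  nodes <- sprintf("V%02d", seq_len(n))
  cmb <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(cmb)) < p
  list(edges = tibble::tibble(gene_1 = cmb[1, keep], gene_2 = cmb[2, keep]),
       nodes = nodes)
}

# Upper-tail hypergeometric probability by direct combinatorial summation
# over all possible overlap counts (independent of stats::phyper).
oracle_hypergeom_upper <- function(k, set_size, universe_size, query_size) {
  js <- k:min(set_size, query_size)
  if (k > min(set_size, query_size)) return(0)
  sum(choose(set_size, js) * choose(universe_size - set_size, query_size - js)) /
    choose(universe_size, query_size)
}

# Benjamini-Hochberg step-up by the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
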