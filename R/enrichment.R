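#' Hypergeometric gene-set over-representation test
#'
#' One-sided (upper tail) hypergeometric test of each library set against a
#' query gene list: with a universe of `N` genes of which `K` belong to the
#' set, and a query of `n` genes with `k` in the set, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Library sets are
#' intersected with the universe before testing; q-values are
#' Benjamini-Hochberg across the library.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param library Named list of character vectors — the gene-set library
#'   (e.g. read with [read_gmt()]).
#' @param universe Character vector: the gene population (e.g. all genes of
#'   the analyzed network).
#' @return Tibble with columns `set`, `set_size`, `overlap`, `p`, `q`,
#'   `genes` (list column of overlap genes), sorted by ascending `p`.
#' @export
#' @examples
#' hypergeom_enrich(c("A", "B", "C"),
#'                  list(s1 = c("A", "B", "X"), s2 = c("Y", "Z")),
#'                  universe = c(LETTERS[1:10], "X", "Y", "Z"))
hypergeom_enrich <- function(query, library, universe) {
  query <- unique(norm_symbols(query))
  universe <- unique(norm_symbols(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (length(query) == 0) abort("`query` must be non-empty.")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort(sprintf("Query genes outside the universe: %s%s.",
                  paste(head(outside, 5), collapse = ", "),
                  if (length(outside) > 5) ", ..." else ""))
  }
  if (!is.list(library) || is.null(names(library)) ||
      any(names(library) == "")) {
    abort("`library` must be a named list of gene sets.")
  }
  rows <- purrr::imap_dfr(library, function(members, nm) {
    members <- intersect(unique(norm_symbols(members)), universe)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- if (length(members) == 0) 1 else {
      phyper(k - 1, length(members), length(universe) - length(members),
             length(query), lower.tail = FALSE)
    }
    tibble::tibble(set = nm, set_size = length(members), overlap = k,
                   p = min(p, 1), genes = list(sort(hit)))
  })
  rows$q <- bh_adjust(rows$p)
  dplyr::arrange(rows[c("set", "set_size", "overlap", "p", "q", "genes")],
                 .data$p, .data$set)
}

#' Membership counts of a query across labelled gene sets
#'
#' For each label set, how many query genes fall in it and which — e.g.
#' partitioning the obesity-annotated genes into hubs, bottlenecks and
#' salt-sensitivity genes.
#'
#' @param query Character vector of genes.
#' @param labels Named list of character vectors (label sets).
#' @return Tibble with `set`, `n`, `genes` (list column).
#' @export
#' @examples
#' cats <- adipose_obesity_categories()
#' overlap_table(cats$gene, split(cats$gene, cats$category))
overlap_table <- function(query, labels) {
  query <- unique(norm_symbols(query))
  if (!is.list(labels) || is.null(names(labels))) {
    abort("`labels` must be a named list of gene sets.")
  }
  purrr::imap_dfr(labels, function(members, nm) {
    hit <- intersect(query, unique(norm_symbols(members)))
    tibble::tibble(set = nm, n = length(hit), genes = list(sort(hit)))
  })
}
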