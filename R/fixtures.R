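#' Curated example tables from an obesity adipose-tissue network study
#'
#' Small tab-separated tables bundled with the package, transcribed from the
#' published results of a visceral adipose-tissue salt-sensitivity network
#' analysis (16 obese vs 14 lean microarray samples). They let the
#' co-expression contrast, connectivity counting, reported/unreported
#' classification and prioritization stages run end-to-end without the
#' original expression data:
#'
#' * `adipose_top_centrality()` — the ten highest-degree genes of the
#'   2691-node protein interaction network with their degree (`dc`) and
#'   normalized betweenness (`bc`).
#' * `adipose_ssg_bottlenecks()` — the 15 salt-sensitivity genes that also
#'   scored as betweenness bottlenecks, with `bc` and `dc`.
#' * `adipose_obesity_categories()` — the obesity-annotated genes
#'   partitioned into `salt_sensitivity` (23), `hub` (16) and `bottleneck`
#'   (84) categories; long format (`category`, `gene`).
#' * `adipose_ssg_status()` — the 23 salt-sensitivity genes co-expressed
#'   with obesity genes and whether each was previously `reported` for
#'   obesity (15) or is `unreported` (8).
#' * `adipose_coexpression_pairs()` — the 56 co-expression partners of the
#'   unreported salt-sensitivity genes, with the pair's Pearson correlation
#'   in obese (`r_obese`) and lean (`r_normal`) samples.
#'
#' @return A tibble (see the per-table descriptions above).
#' @name adipose_fixtures
NULL

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "sspin", mustWork = FALSE)
  if (path == "") {
    # During development the package root may be the working directory.
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(sprintf("Fixture '%s' not found.", file))
  path
}

read_fixture <- function(file) {
  readr::read_tsv(fixture_path(file), show_col_types = FALSE, progress = FALSE)
}

#' @rdname adipose_fixtures
#' @export
adipose_top_centrality <- function() read_fixture("adipose_top_centrality.tsv")

#' @rdname adipose_fixtures
#' @export
adipose_ssg_bottlenecks <- function() read_fixture("adipose_ssg_bottlenecks.tsv")

#' @rdname adipose_fixtures
#' @export
adipose_obesity_categories <- function() read_fixture("adipose_obesity_categories.tsv")

#' @rdname adipose_fixtures
#' @export
adipose_ssg_status <- function() read_fixture("adipose_ssg_status.tsv")

#' @rdname adipose_fixtures
#' @export
adipose_coexpression_pairs <- function() read_fixture("adipose_coexpression_pairs.tsv")
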