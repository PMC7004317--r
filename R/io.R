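# File formats: TSV everywhere, SIF and GraphML for networks, GMT for gene
# set libraries, one-symbol-per-line text for plain gene lists.

#' Read / write an expression matrix as TSV
#'
#' The format is a header line of sample IDs with a leading `gene` column,
#' one row per gene, tab-separated.
#'
#' @param path File path.
#' @return `read_expression()`: tibble with `gene` plus sample columns.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(out)[1] != "gene") names(out)[1] <- "gene"
  out$gene <- norm_symbols(out$gene)
  out
}

#' @rdname read_expression
#' @param expression Tibble with `gene` plus sample columns.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata (sample_id, condition) as TSV
#'
#' @param path File path.
#' @return Tibble with `sample_id` and `condition`.
#' @export
read_metadata <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "condition") %in% names(out))) {
    abort("Metadata file must have columns `sample_id` and `condition`.")
  }
  out
}

#' @rdname read_metadata
#' @param metadata Tibble with `sample_id` and `condition`.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read an interaction edge list (two-column TSV or SIF)
#'
#' SIF lines are `source<TAB>interaction<TAB>target...` (possibly several
#' targets per line); two-column files are plain endpoint pairs with or
#' without a header. The result is cleaned with [clean_network()].
#'
#' @param path File path.
#' @param format `"auto"` (default: `.sif` extension means SIF), `"tsv"` or
#'   `"sif"`.
#' @return Cleaned edge tibble.
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    pairs <- purrr::map_dfr(strsplit(lines, "\t| +"), function(f) {
      f <- f[nzchar(f)]
      if (length(f) < 3) return(tibble::tibble())
      tibble::tibble(gene_1 = f[1], gene_2 = f[-(1:2)])
    })
    return(clean_network(pairs))
  }
  first <- readLines(path, n = 1)
  has_header <- grepl("gene|source|from|node", tolower(first))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  clean_network(df)
}

#' @rdname read_edge_list
#' @param edges Cleaned edge tibble.
#' @param interaction Interaction type string written in the SIF middle
#'   column.
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  writeLines(sprintf("%s\t%s\t%s", edges$gene_1, interaction, edges$gene_2),
             path)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param edges Cleaned edge tibble; an `r` column, if present, is exported
#'   as the `weight` edge attribute.
#' @param path Output path.
#' @param nodes Optional full node set including isolates.
#' @export
write_graphml <- function(edges, path, nodes = NULL) {
  g <- as_igraph(edges[c("gene_1", "gene_2")], nodes)
  if ("r" %in% names(edges)) {
    igraph::E(g)$weight <- edges$r
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read / write gene-set libraries in GMT format
#'
#' GMT lines are `set_name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3) abort("GMT lines need a name, a description and members.")
    norm_symbols(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) abort("Duplicate set names in GMT file.")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read / write plain one-symbol-per-line gene lists
#'
#' @param path File path.
#' @return Character vector of upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  norm_symbols(x[nzchar(x)])
}

#' @rdname read_gene_list
#' @param genes Character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(norm_symbols(genes), path)
  invisible(path)
}

#' Write / read a co-expression contrast table
#'
#' Serialized as TSV with correlations to 4 decimal places (the precision
#' used throughout the printed contrast tables); reading restores a
#' `coexpr_contrast` tibble.
#'
#' @param contrast A `coexpr_contrast` tibble (see [contrast_conditions()]).
#' @param path File path.
#' @export
write_contrast <- function(contrast, path) {
  out <- contrast
  out$r_disease <- sprintf("%.4f", out$r_disease)
  out$r_control <- ifelse(is.na(out$r_control), "NA",
                          sprintf("%.4f", out$r_control))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_contrast
#' @export
read_contrast <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  if (!all(c("gene_1", "gene_2", "r_disease", "r_control") %in% names(out))) {
    abort("Contrast file must have columns gene_1, gene_2, r_disease, r_control.")
  }
  class(out) <- c("coexpr_contrast", class(out))
  out
}

#' Write a full simulation to a directory
#'
#' Emits `expression.tsv`, `metadata.tsv`, `truth_de_genes.txt`,
#' `truth_block_pairs.tsv` for an expression simulation, and `edges.tsv`,
#' `edges.sif`, `truth_hubs.txt`, `truth_bridges.txt` for a network
#' simulation.
#'
#' @param sim Result of [simulate_expression()] or [simulate_network()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim, "expression_sim")) {
    write_expression(sim$expression, file.path(dir, "expression.tsv"))
    write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
    write_gene_list(sim$truth$de_genes, file.path(dir, "truth_de_genes.txt"))
    readr::write_tsv(sim$truth$block_pairs,
                     file.path(dir, "truth_block_pairs.tsv"), progress = FALSE)
  } else if (inherits(sim, "network_sim")) {
    write_edge_list(sim$edges, file.path(dir, "edges.tsv"))
    write_sif(sim$edges, file.path(dir, "edges.sif"))
    write_gene_list(sim$truth$planted_hubs, file.path(dir, "truth_hubs.txt"))
    write_gene_list(sim$truth$planted_bridges,
                    file.path(dir, "truth_bridges.txt"))
  } else {
    abort("`sim` must come from simulate_expression() or simulate_network().")
  }
  invisible(dir)
}
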