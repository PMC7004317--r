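#' Pearson correlation between two expression profiles
#'
#' Sample Pearson correlation coefficient; returns `NA` when either profile
#' has zero variance (the correlation is undefined, never 0).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A number in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  if (length(x) < 3) abort("Pearson correlation needs at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Pairwise Pearson correlation map for one condition
#'
#' Computes the full symmetric correlation matrix over the requested genes,
#' using only the samples of one condition. This is the per-condition
#' correlation map the co-expression analysis contrasts: correlations are
#' computed separately in the disease and control sample sets over the
#' SS-PIN gene panel.
#'
#' @param expression,metadata Expression table and sample metadata as in
#'   [deg_test()].
#' @param condition `"case"` or `"control"` — which samples to use.
#' @param genes Genes to correlate; defaults to all genes in `expression`.
#'   Genes absent from the matrix are skipped with a warning.
#' @return An object of class `correlation_map`: list with `condition`,
#'   `genes`, and `r`, the symmetric correlation matrix (`NA` where a gene
#'   has zero variance in the condition's samples). Supports [tidy()].
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 20, n_de = 0, seed = 3))
#' cmap <- correlation_map(sim$expression, sim$metadata, "case")
#' cmap$r[1:3, 1:3]
correlation_map <- function(expression, metadata,
                            condition = c("case", "control"),
                            genes = NULL) {
  condition <- match.arg(condition)
  em <- as_expression_matrix(expression, metadata)
  genes <- if (is.null(genes)) em$genes else unique(norm_symbols(genes))
  missing <- setdiff(genes, em$genes)
  if (length(missing)) {
    warn(sprintf("Skipping %d gene(s) absent from the expression matrix: %s%s.",
                 length(missing), paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
    genes <- setdiff(genes, missing)
  }
  in_cond <- em$condition == condition
  if (sum(in_cond) < 3) {
    abort(sprintf("Condition '%s' has fewer than 3 samples.", condition))
  }
  values <- t(em$values[genes, in_cond, drop = FALSE])
  flat <- apply(values, 2, sd) == 0
  r <- suppressWarnings(cor(values))
  if (any(flat)) {
    warn(sprintf("%d gene(s) have zero variance in '%s' samples; their correlations are NA.",
                 sum(flat), condition))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  structure(list(condition = condition, genes = genes, r = r),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("Correlation map: %d genes, condition '%s' (%d pairs)\n",
              length(x$genes), x$condition,
              choose(length(x$genes), 2)))
  invisible(x)
}

#' Threshold a correlation map into a co-expression edge list
#'
#' Keeps the gene pairs whose correlation meets the threshold — by default
#' `r >= 0.8` in the positive direction only, the screening rule for the
#' disease co-expression network. `sign = "absolute"` keeps `|r| >= threshold`
#' instead. Missing correlations never pass.
#'
#' @param map A `correlation_map`.
#' @param threshold Correlation threshold in `(0, 1]` (default 0.8).
#' @param sign `"positive"` (default) or `"absolute"`.
#' @return Tibble with `gene_1`, `gene_2`, `r`, sorted by decreasing `r`.
#' @export
threshold_network <- function(map, threshold = 0.8,
                              sign = c("positive", "absolute")) {
  sign <- match.arg(sign)
  stopifnot(inherits(map, "correlation_map"))
  check_number(threshold, "threshold", min = 0, max = 1)
  if (threshold <= 0) abort("`threshold` must be in (0, 1].")
  long <- tidy(map)
  keep <- if (sign == "positive") long$r >= threshold else abs(long$r) >= threshold
  out <- long[!is.na(long$r) & keep, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$r), .data$gene_1, .data$gene_2)
}

#' Contrast disease co-expression edges against the control condition
#'
#' For every edge of the thresholded disease co-expression network, attaches
#' the correlation of the same gene pair in the control condition, producing
#' the disease-versus-control contrast table used to spot disease-specific
#' co-expression.
#'
#' @param disease_edges Tibble from [threshold_network()] (columns `gene_1`,
#'   `gene_2`, `r`).
#' @param control_map A `correlation_map` for the control condition covering
#'   the same genes; pairs absent from it get `r_control = NA` with a
#'   warning.
#' @return A `coexpr_contrast` tibble with columns `gene_1`, `gene_2`,
#'   `r_disease`, `r_control`. Supports [autoplot()].
#' @export
contrast_conditions <- function(disease_edges, control_map) {
  stopifnot(inherits(control_map, "correlation_map"))
  if (!all(c("gene_1", "gene_2", "r") %in% names(disease_edges))) {
    abort("`disease_edges` must have columns gene_1, gene_2, r.")
  }
  r_control <- rep(NA_real_, nrow(disease_edges))
  in_map <- disease_edges$gene_1 %in% control_map$genes &
    disease_edges$gene_2 %in% control_map$genes
  if (any(in_map)) {
    r_control[in_map] <- control_map$r[cbind(disease_edges$gene_1[in_map],
                                             disease_edges$gene_2[in_map])]
  }
  if (any(!in_map)) {
    warn(sprintf("%d pair(s) missing from the control map; r_control set to NA.",
                 sum(!in_map)))
  }
  out <- tibble::tibble(gene_1 = disease_edges$gene_1,
                        gene_2 = disease_edges$gene_2,
                        r_disease = disease_edges$r,
                        r_control = r_control)
  class(out) <- c("coexpr_contrast", class(out))
  out
}

#' Count co-expression partners of candidate genes
#'
#' For each candidate, counts the contrast rows incident to it — its direct
#' connectivity in the disease co-expression network. Candidates appearing
#' in no row get 0.
#'
#' @param contrast A contrast table (any data frame with `gene_1`, `gene_2`
#'   columns, e.g. from [contrast_conditions()] or
#'   [adipose_coexpression_pairs()]).
#' @param candidates Character vector of candidate gene symbols.
#' @return Tibble with `gene`, `connectivity`, sorted by decreasing count
#'   then alphabetically.
#' @export
#' @examples
#' pairs <- adipose_coexpression_pairs()
#' connectivity_counts(pairs, c("ENPEP", "WNK1", "CTSA"))
connectivity_counts <- function(contrast, candidates) {
  if (!all(c("gene_1", "gene_2") %in% names(contrast))) {
    abort("`contrast` must have columns gene_1 and gene_2.")
  }
  candidates <- unique(norm_symbols(candidates))
  counts <- vapply(candidates, function(g) {
    sum(contrast$gene_1 == g | contrast$gene_2 == g)
  }, integer(1))
  tibble::tibble(gene = candidates, connectivity = unname(counts)) |>
    dplyr::arrange(dplyr::desc(.data$connectivity), .data$gene)
}

#' Classify genes as reported or unreported for a disease
#'
#' A gene is "reported" when it belongs to the disease annotation set (e.g.
#' the obesity-annotated genes); otherwise it is an unreported candidate.
#'
#' @param genes Character vector of genes to classify.
#' @param annotation Character vector — the disease annotation gene set.
#' @return Tibble with `gene` and `reported` (logical).
#' @export
classify_reported <- function(genes, annotation) {
  genes <- unique(norm_symbols(genes))
  annotation <- norm_symbols(annotation)
  tibble::tibble(gene = genes, reported = genes %in% annotation)
}

#' Prioritize unreported candidates by co-expression connectivity
#'
#' Selects the unreported genes whose connectivity in the disease
#' co-expression network reaches `min_connectivity` (default 3), ranked by
#' connectivity descending with alphabetical tie-break. Reported genes are
#' never selected — the aim is novel candidates.
#'
#' @param connectivity Tibble from [connectivity_counts()] (or named counts).
#' @param reported Tibble from [classify_reported()] (or named logical).
#' @param min_connectivity Minimum partner count for selection.
#' @return A `prioritization` tibble with columns `gene`, `connectivity`,
#'   `reported`, `selected`, ranked. Supports [autoplot()].
#' @export
prioritize_candidates <- function(connectivity, reported, min_connectivity = 3) {
  check_number(min_connectivity, "min_connectivity", min = 0)
  if (!is.data.frame(connectivity)) {
    connectivity <- tibble::tibble(gene = names(connectivity),
                                   connectivity = as.integer(connectivity))
  }
  if (!is.data.frame(reported)) {
    reported <- tibble::tibble(gene = names(reported),
                               reported = as.logical(reported))
  }
  out <- dplyr::left_join(connectivity, reported, by = "gene")
  out$reported[is.na(out$reported)] <- FALSE
  out$selected <- !out$reported & out$connectivity >= min_connectivity
  out <- dplyr::arrange(out, dplyr::desc(.data$connectivity), .data$gene)
  class(out) <- c("prioritization", class(out))
  attr(out, "min_connectivity") <- min_connectivity
  out
}
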