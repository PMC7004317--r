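#' Per-gene two-sample t-tests between conditions
#'
#' Runs an unpaired two-sample t-test for every gene of a normalized log2
#' expression table, case versus control. The statistic is
#' `(mean_case - mean_control) / SE` with the pooled-variance (Student) form
#' by default; set `welch = TRUE` for the unequal-variance form. P-values are
#' two-sided. Degenerate genes are handled explicitly: zero variance in both
#' groups with equal means gives `t = 0, p = 1`; zero pooled variance with
#' unequal means gives `p = 0` with a warning (the groups are perfectly
#' separated, so any significance threshold is passed).
#'
#' @param expression Tibble/data frame with a `gene` column followed by one
#'   numeric column per sample (the format written by [write_expression()]).
#' @param metadata Tibble with columns `sample_id` and `condition`
#'   (`"control"`/`"case"`); every expression sample column must be listed.
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @param alpha Significance threshold used for the `passes` flag.
#' @param use_adjusted Apply `alpha` to BH-adjusted p-values (default) or to
#'   raw p-values.
#'
#' @return A `deg_table` tibble with columns `gene`, `mean_control`,
#'   `mean_case`, `t`, `p`, `p_adj`, `passes`, ordered as the input genes.
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 50, n_de = 5, seed = 1))
#' degs <- deg_test(sim$expression, sim$metadata)
#' dplyr::filter(degs, passes)
deg_test <- function(expression, metadata, welch = FALSE,
                     alpha = 0.05, use_adjusted = TRUE) {
  em <- as_expression_matrix(expression, metadata)
  n1 <- sum(em$condition == "control")
  n2 <- sum(em$condition == "case")
  if (n1 < 2 || n2 < 2) {
    abort("Each condition needs at least 2 samples for a t-test.")
  }
  x <- em$values[, em$condition == "control", drop = FALSE]
  y <- em$values[, em$condition == "case", drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)

  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }

  tt <- (m2 - m1) / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)

  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    tt[eq] <- 0
    p[eq] <- 1
    sep <- degen & (m1 != m2)
    if (any(sep)) {
      warn(sprintf(
        "%d gene(s) have zero within-group variance but unequal means; p recorded as 0.",
        sum(sep)))
      tt[sep] <- sign(m2[sep] - m1[sep]) * Inf
      p[sep] <- 0
    }
  }

  p_adj <- bh_adjust(p)
  out <- tibble::tibble(
    gene = em$genes, mean_control = unname(m1), mean_case = unname(m2),
    t = unname(tt), p = unname(p), p_adj = unname(p_adj),
    passes = unname((if (use_adjusted) p_adj else p) <= alpha)
  )
  class(out) <- c("deg_table", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "use_adjusted") <- use_adjusted
  attr(out, "welch") <- welch
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: sort
#' ascending, set `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, and return in
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    abort("`p` values must all lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes from a DEG table
#'
#' @param deg_table Result of [deg_test()].
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Threshold BH-adjusted p-values (default) or raw ones.
#' @return Character vector of gene symbols passing the threshold.
#' @export
select_degs <- function(deg_table, alpha = 0.05, use_adjusted = TRUE) {
  check_probability(alpha, "alpha")
  cols <- c("gene", "p", "p_adj")
  if (!all(cols %in% names(deg_table))) {
    abort("`deg_table` must have columns gene, p and p_adj (see deg_test()).")
  }
  pcol <- if (use_adjusted) deg_table$p_adj else deg_table$p
  deg_table$gene[pcol <= alpha]
}

# Validate and convert the tabular expression + metadata pair into the
# internal genes-by-samples matrix representation.
as_expression_matrix <- function(expression, metadata) {
  if (!is.data.frame(expression) || !"gene" %in% names(expression)) {
    abort("`expression` must be a data frame with a `gene` column.")
  }
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "condition") %in% names(metadata))) {
    abort("`metadata` must have columns `sample_id` and `condition`.")
  }
  genes <- norm_symbols(expression$gene)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(sprintf("Duplicate gene symbols after upper-casing: %s.",
                  paste(head(dup, 5), collapse = ", ")))
  }
  samples <- setdiff(names(expression), "gene")
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta)) {
    abort(sprintf("Samples without condition metadata: %s.",
                  paste(head(missing_meta, 5), collapse = ", ")))
  }
  cond <- metadata$condition[match(samples, metadata$sample_id)]
  bad <- setdiff(unique(cond), c("control", "case"))
  if (length(bad)) {
    abort(sprintf("Conditions must be 'control' or 'case'; found: %s.",
                  paste(bad, collapse = ", ")))
  }
  values <- as.matrix(expression[samples])
  if (!is.numeric(values)) abort("Expression values must be numeric.")
  rownames(values) <- genes
  list(genes = genes, samples = samples, condition = cond, values = values)
}
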