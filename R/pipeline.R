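#' Pipeline configuration
#'
#' Collects every tunable parameter of [run_pipeline()] with the defaults
#' used throughout the analysis: DEG selection at BH-adjusted p <= 0.05 by
#' Student's t-test, hub cutoff at mean + 2 SD of degree, bottlenecks as the
#' top betweenness quartile, disease co-expression at Pearson r >= 0.8
#' (positive direction), and candidate selection at >= 3 co-expression
#' partners.
#'
#' @param alpha DEG significance threshold.
#' @param use_adjusted Threshold BH-adjusted p-values (default) or raw.
#' @param welch Use Welch's t-test instead of Student's.
#' @param hub_multiplier SD multiplier of the hub degree cutoff.
#' @param sd_mode `"sample"` or `"population"` SD in the hub cutoff.
#' @param bottleneck_quantile Top betweenness fraction called bottleneck.
#' @param coexpr_threshold Disease co-expression correlation threshold.
#' @param coexpr_sign `"positive"` or `"absolute"` thresholding.
#' @param min_connectivity Minimum co-expression partners for a prioritized
#'   candidate.
#' @param seed Integer seed for any stochastic input generation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, use_adjusted = TRUE, welch = FALSE,
                            hub_multiplier = 2,
                            sd_mode = c("sample", "population"),
                            bottleneck_quantile = 0.25,
                            coexpr_threshold = 0.8,
                            coexpr_sign = c("positive", "absolute"),
                            min_connectivity = 3, seed = 1L) {
  check_probability(alpha, "alpha")
  check_number(hub_multiplier, "hub_multiplier", min = 0)
  check_probability(bottleneck_quantile, "bottleneck_quantile")
  check_number(coexpr_threshold, "coexpr_threshold", min = 0, max = 1)
  if (coexpr_threshold <= 0) abort("`coexpr_threshold` must be in (0, 1].")
  check_number(min_connectivity, "min_connectivity", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(alpha = alpha, use_adjusted = isTRUE(use_adjusted),
         welch = isTRUE(welch), hub_multiplier = hub_multiplier,
         sd_mode = match.arg(sd_mode),
         bottleneck_quantile = bottleneck_quantile,
         coexpr_threshold = coexpr_threshold,
         coexpr_sign = match.arg(coexpr_sign),
         min_connectivity = min_connectivity, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full salt-sensitivity network pipeline
#'
#' Orchestrates every stage: DEG selection, PIN cleaning and restriction to
#' DEGs, centralities, hub and bottleneck calls, HBS assembly, SS-PIN
#' extraction, per-condition correlation maps over the SS-PIN genes,
#' disease-network thresholding and control contrast, SSG connectivity
#' counting, reported/unreported classification, prioritization, and
#' (optionally) hypergeometric enrichment. Every effective parameter and
#' stage outcome is recorded in the run log; a stage failure aborts with the
#' stage name and cause.
#'
#' @param expression,metadata Expression table and sample metadata (see
#'   [deg_test()]).
#' @param edges Raw interaction edge list (cleaned internally).
#' @param ssgs Character vector of salt-sensitivity gene symbols.
#' @param annotation Character vector of disease-annotated genes (used for
#'   reported/unreported classification); may be empty.
#' @param enrichment_library Optional named list of gene sets tested for
#'   over-representation of the HBS union.
#' @param enrichment_universe `"network"` (default: the PIN node set) or a
#'   character vector of genes.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage's tables are
#'   written there as TSV/SIF and a `run_summary.tsv` is emitted.
#' @return An object of class `sspin_run`: list with `config`, `stages` (all
#'   intermediate objects), `log` (character), and `summary` (one-row
#'   tibble). Supports [tidy()] (prioritization table) and [glance()].
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 60, n_de = 10, seed = 7,
#'                          network = network_config(n_nodes = 60, n_hubs = 2,
#'                                                   hub_degree = 20))
#' study <- simulate_study(cfg)
#' run <- run_pipeline(study$expression, study$metadata, study$edges,
#'                     ssgs = study$truth$de_genes[1:5],
#'                     config = pipeline_config(alpha = 1))
#' glance(run)
run_pipeline <- function(expression, metadata, edges, ssgs,
                         annotation = character(),
                         enrichment_library = NULL,
                         enrichment_universe = "network",
                         config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(c(name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  note("parameters: alpha=%g use_adjusted=%s welch=%s hub_multiplier=%g sd_mode=%s",
       config$alpha, config$use_adjusted, config$welch,
       config$hub_multiplier, config$sd_mode)
  note("parameters: bottleneck_quantile=%g coexpr_threshold=%g coexpr_sign=%s min_connectivity=%g seed=%d",
       config$bottleneck_quantile, config$coexpr_threshold,
       config$coexpr_sign, config$min_connectivity, config$seed)

  ssgs <- unique(norm_symbols(ssgs))
  annotation <- unique(norm_symbols(annotation))

  degs_tbl <- stage("deg", deg_test(expression, metadata, welch = config$welch,
                                    alpha = config$alpha,
                                    use_adjusted = config$use_adjusted))
  degs <- select_degs(degs_tbl, config$alpha, config$use_adjusted)
  note("deg: %d/%d genes pass (alpha=%g, %s p)", length(degs), nrow(degs_tbl),
       config$alpha, if (config$use_adjusted) "adjusted" else "raw")

  pin_all <- stage("network", clean_network(edges))
  pin <- stage("network", induced_subgraph(pin_all, degs))
  pin_nodes <- union(pin$gene_1, pin$gene_2)
  note("network: PIN %d nodes, %d edges (edge-node ratio %.2f)",
       length(pin_nodes), nrow(pin),
       if (length(pin_nodes)) nrow(pin) / length(pin_nodes) else NA_real_)

  cents <- stage("centrality", centrality_table(pin, nodes = pin_nodes))
  hub_call <- stage("hubs", classify_hubs(cents, config$hub_multiplier,
                                          config$sd_mode))
  bottlenecks <- stage("bottlenecks",
                       classify_bottlenecks(cents, config$bottleneck_quantile))
  note("hubs: %d at DC > %.3f; bottlenecks: %d at top %g quantile",
       length(hub_call$hubs), hub_call$cutoff$cutoff, length(bottlenecks),
       config$bottleneck_quantile)

  hbs <- stage("sspin", assemble_hbs(hub_call$hubs, bottlenecks, ssgs))
  sspin_edges <- stage("sspin", extract_sspin(pin, hbs))
  unmapped_ssgs <- setdiff(ssgs, pin_nodes)
  note("sspin: HBS union %d genes (%d SSGs unmapped to the PIN), %d edges",
       length(hbs$union), length(unmapped_ssgs), nrow(sspin_edges))

  panel <- intersect(hbs$union, expression_genes(expression))
  case_map <- stage("coexpression",
                    correlation_map(expression, metadata, "case", panel))
  control_map <- stage("coexpression",
                       correlation_map(expression, metadata, "control", panel))
  disease_edges <- stage("coexpression",
                         threshold_network(case_map, config$coexpr_threshold,
                                           config$coexpr_sign))
  contrast <- stage("contrast",
                    contrast_conditions(disease_edges, control_map))
  note("coexpression: %d genes in panel, %d disease pairs at r >= %g",
       length(panel), nrow(contrast), config$coexpr_threshold)

  coexpr_ssgs <- intersect(ssgs, union(contrast$gene_1, contrast$gene_2))
  connectivity <- stage("prioritize",
                        connectivity_counts(contrast, coexpr_ssgs))
  reported <- stage("prioritize", classify_reported(coexpr_ssgs, annotation))
  prior <- stage("prioritize",
                 prioritize_candidates(connectivity, reported,
                                       config$min_connectivity))
  selected <- prior$gene[prior$selected]
  note("prioritize: %d co-expressed SSGs (%d unreported) -> %d selected: %s",
       length(coexpr_ssgs), sum(!prior$reported), length(selected),
       paste(selected, collapse = ", "))

  enrich <- NULL
  if (!is.null(enrichment_library) && length(hbs$union)) {
    universe <- if (identical(enrichment_universe, "network")) {
      union(pin_nodes, hbs$union)
    } else {
      unique(norm_symbols(enrichment_universe))
    }
    enrich <- stage("enrich",
                    hypergeom_enrich(intersect(hbs$union, universe),
                                     enrichment_library, universe))
    note("enrich: %d sets tested against a universe of %d genes",
         nrow(enrich), length(universe))
  }

  summary <- tibble::tibble(
    n_genes = nrow(degs_tbl), n_degs = length(degs),
    pin_nodes = length(pin_nodes), pin_edges = nrow(pin),
    n_hubs = length(hub_call$hubs), n_bottlenecks = length(bottlenecks),
    n_ssgs = length(ssgs), hbs_union = length(hbs$union),
    sspin_edges = nrow(sspin_edges), coexpr_pairs = nrow(contrast),
    coexpr_ssgs = length(coexpr_ssgs), n_selected = length(selected))

  run <- structure(
    list(config = config,
         stages = list(degs = degs_tbl, deg_genes = degs, pin = pin,
                       centrality = cents, hub_call = hub_call,
                       bottlenecks = bottlenecks, hbs = hbs,
                       sspin = sspin_edges, unmapped_ssgs = unmapped_ssgs,
                       case_map = case_map, control_map = control_map,
                       contrast = contrast, connectivity = connectivity,
                       reported = reported, prioritization = prior,
                       enrichment = enrich),
         log = log, summary = summary),
    class = "sspin_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

expression_genes <- function(expression) norm_symbols(expression$gene)

# Emit every stage table of a finished run; same run + same seed gives
# byte-identical files.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- run$stages
  readr::write_tsv(st$degs, file.path(out_dir, "deg_table.tsv"), progress = FALSE)
  write_gene_list(st$deg_genes, file.path(out_dir, "deg_genes.txt"))
  write_edge_list(st$pin, file.path(out_dir, "pin_edges.tsv"))
  write_sif(st$pin, file.path(out_dir, "pin_edges.sif"))
  readr::write_tsv(st$centrality, file.path(out_dir, "centrality.tsv"),
                   progress = FALSE)
  write_gene_list(st$hub_call$hubs, file.path(out_dir, "hubs.txt"))
  write_gene_list(st$bottlenecks, file.path(out_dir, "bottlenecks.txt"))
  write_gene_list(st$hbs$union, file.path(out_dir, "hbs_union.txt"))
  write_edge_list(st$sspin, file.path(out_dir, "sspin_edges.tsv"))
  write_graphml(st$sspin, file.path(out_dir, "sspin.graphml"))
  write_contrast(st$contrast, file.path(out_dir, "coexpression_contrast.tsv"))
  readr::write_tsv(st$prioritization, file.path(out_dir, "prioritization.tsv"),
                   progress = FALSE)
  if (!is.null(st$enrichment)) {
    flat <- st$enrichment
    flat$genes <- vapply(flat$genes, paste, character(1), collapse = ",")
    readr::write_tsv(flat, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$summary, file.path(out_dir, "run_summary.tsv"),
                   progress = FALSE)
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.sspin_run <- function(x, ...) {
  cat("Salt-sensitivity network pipeline run\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
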