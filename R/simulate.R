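#' Configure a synthetic two-condition expression + interaction study
#'
#' Builds the configuration object consumed by [simulate_expression()] and
#' [simulate_network()]. The defaults emulate the visceral-adipose microarray
#' design the pipeline was built around: 14 control (lean) and 16 case (obese)
#' samples on a log2 scale, a set of planted mean-shift DE genes, one
#' case-only co-expression block, and a modular interaction network with
#' planted high-degree hubs and inter-community bridge nodes.
#'
#' @param n_genes Number of genes in the expression matrix.
#' @param n_control,n_case Samples per condition (each at least 3).
#' @param n_de Number of planted differentially expressed genes.
#' @param de_shift Mean shift (log2 units) added to case samples of DE genes.
#' @param blocks List of planted co-expression blocks, each created with
#'   [coexpression_block()].
#' @param noise_sd Residual standard deviation in log2 units.
#' @param network Network sub-configuration from [network_config()].
#' @param seed Single integer seed; all draws in both generators are derived
#'   deterministically from it.
#'
#' @return A list of class `simulation_config`.
#' @seealso [simulate_expression()], [simulate_network()]
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 100, n_de = 10, seed = 42)
#' sim <- simulate_expression(cfg)
#' dim(sim$expression)
simulation_config <- function(n_genes = 500,
                              n_control = 14,
                              n_case = 16,
                              n_de = 50,
                              de_shift = 2,
                              blocks = list(coexpression_block(10, 0.9, "case_only")),
                              noise_sd = 0.5,
                              network = network_config(),
                              seed = 1L) {
  check_number(n_genes, "n_genes", min = 1, integerish = TRUE)
  check_number(n_control, "n_control", min = 3, integerish = TRUE)
  check_number(n_case, "n_case", min = 3, integerish = TRUE)
  check_number(n_de, "n_de", min = 0, integerish = TRUE)
  check_number(de_shift, "de_shift")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  if (n_de > n_genes) {
    abort("`n_de` must not exceed `n_genes`.")
  }
  if (!is.list(blocks) || !all(vapply(blocks, inherits, logical(1), "coexpression_block"))) {
    abort("`blocks` must be a list of coexpression_block() objects.")
  }
  for (b in blocks) {
    if (b$size > n_genes) {
      abort("`blocks`: block_size must not exceed `n_genes`.")
    }
  }
  total_block <- sum(vapply(blocks, function(b) b$size, numeric(1)))
  if (n_de + total_block > n_genes) {
    abort("`blocks`: DE genes plus block genes exceed `n_genes`; blocks are planted disjointly.")
  }
  if (!inherits(network, "network_config")) {
    abort("`network` must be created with network_config().")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_control = as.integer(n_control),
         n_case = as.integer(n_case), n_de = as.integer(n_de),
         de_shift = de_shift, blocks = blocks, noise_sd = noise_sd,
         network = network, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Describe one planted co-expression block
#'
#' A block is a set of genes sharing a latent factor in the active condition,
#' so that every within-block gene pair has expected Pearson correlation
#' `rho` there. `case_only` blocks are the disease-specific signal the
#' differential co-expression contrast is designed to detect: correlated in
#' case samples, independent in controls.
#'
#' @param size Number of genes in the block.
#' @param rho Target pairwise correlation, in `[0, 1)`.
#' @param condition `"case_only"` or `"both"`.
#' @return A list of class `coexpression_block`.
#' @export
coexpression_block <- function(size, rho, condition = c("case_only", "both")) {
  check_number(size, "block_size", min = 2, integerish = TRUE)
  check_number(rho, "rho", min = 0, max = 1)
  if (rho >= 1) abort("`rho` must be strictly below 1.")
  condition <- match.arg(condition)
  structure(list(size = as.integer(size), rho = rho, condition = condition),
            class = "coexpression_block")
}

#' Configure the synthetic interaction network
#'
#' Communities are internally Erdos-Renyi with edge probability
#' `background_edge_prob` and are connected to one another only through the
#' designated bridge nodes, which guarantees the bridges high betweenness.
#' Hub nodes are wired to approximately `hub_degree` partners by preferential
#' attachment, mimicking the heavy-tailed degree distribution of protein
#' interaction networks.
#'
#' @param n_nodes Total node count.
#' @param n_hubs Number of planted high-degree hubs.
#' @param hub_degree Target degree of each planted hub (must be < `n_nodes`).
#' @param n_communities Number of dense communities.
#' @param n_bridges Number of planted bridge nodes joining all communities.
#' @param background_edge_prob Within-community edge probability.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_nodes = 300,
                           n_hubs = 5,
                           hub_degree = 60,
                           n_communities = 3,
                           n_bridges = 2,
                           background_edge_prob = 0.05) {
  check_number(n_nodes, "n_nodes", min = 1, integerish = TRUE)
  check_number(n_hubs, "n_hubs", min = 0, integerish = TRUE)
  check_number(hub_degree, "hub_degree", min = 0, integerish = TRUE)
  check_number(n_communities, "n_communities", min = 1, integerish = TRUE)
  check_number(n_bridges, "n_bridges", min = 0, integerish = TRUE)
  check_probability(background_edge_prob, "background_edge_prob")
  if (hub_degree >= n_nodes) {
    abort("`hub_degree` must be smaller than `n_nodes`.")
  }
  if (n_hubs + n_bridges >= n_nodes) {
    abort("`n_hubs` plus `n_bridges` must leave room for community nodes.")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_hubs = as.integer(n_hubs),
         hub_degree = as.integer(hub_degree),
         n_communities = as.integer(n_communities),
         n_bridges = as.integer(n_bridges),
         background_edge_prob = background_edge_prob),
    class = "network_config"
  )
}

#' Simulate a two-condition log2 expression matrix with planted structure
#'
#' Every gene gets a constant baseline drawn once from N(8, 2) (a typical
#' log2 microarray scale) plus Gaussian noise of sd `noise_sd`. Planted DE
#' genes additionally get a `de_shift` mean shift in case samples. For each
#' co-expression block, samples of the active condition(s) are generated as
#' `baseline + noise_sd * (sqrt(rho) * f_s + sqrt(1 - rho) * eps)` with a
#' shared per-sample latent factor `f_s`, so the expected within-block
#' pairwise Pearson correlation is exactly `rho`. Identical configurations
#' (including the seed) give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `expression_sim` with elements
#'   * `expression`: tibble, one `gene` column plus one column per sample;
#'   * `metadata`: tibble with `sample_id` and `condition` (`control`/`case`);
#'   * `truth`: list with `de_genes`, `block_genes` (list per block),
#'     `block_pairs` (tibble `gene_1`, `gene_2`, `rho`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, offset = 0L, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    samples <- c(sprintf("CTRL%03d", seq_len(config$n_control)),
                 sprintf("CASE%03d", seq_len(config$n_case)))
    condition <- rep(c("control", "case"), c(config$n_control, config$n_case))
    is_case <- condition == "case"

    baseline <- rnorm(config$n_genes, mean = 8, sd = 2)
    noise <- matrix(rnorm(config$n_genes * length(samples)),
                    nrow = config$n_genes)

    # Planted gene assignment: DE genes and blocks drawn without replacement
    # from disjoint slices of the gene pool, so truth sets never overlap.
    pool <- sample(genes)
    de_genes <- sort(head(pool, config$n_de))
    pool <- pool[setdiff(seq_along(pool), seq_len(config$n_de))]
    block_genes <- list()
    for (b in config$blocks) {
      block_genes[[length(block_genes) + 1L]] <- sort(head(pool, b$size))
      pool <- pool[setdiff(seq_along(pool), seq_len(b$size))]
    }

    for (i in seq_along(config$blocks)) {
      b <- config$blocks[[i]]
      active <- if (b$condition == "both") rep(TRUE, length(samples)) else is_case
      idx <- match(block_genes[[i]], genes)
      f <- rnorm(sum(active))
      noise[idx, active] <- sqrt(b$rho) * matrix(f, nrow = length(idx),
                                                 ncol = sum(active), byrow = TRUE) +
        sqrt(1 - b$rho) * matrix(rnorm(length(idx) * sum(active)), nrow = length(idx))
    }

    values <- baseline + config$noise_sd * noise
    values[match(de_genes, genes), is_case] <-
      values[match(de_genes, genes), is_case] + config$de_shift

    block_pairs <- purrr::map2_dfr(block_genes, config$blocks, function(g, b) {
      if (length(g) < 2) return(tibble::tibble())
      cmb <- utils::combn(g, 2)
      tibble::tibble(gene_1 = cmb[1, ], gene_2 = cmb[2, ], rho = b$rho)
    })
    if (nrow(block_pairs)) block_pairs <- order_pairs(block_pairs)

    expr <- tibble::as_tibble(as.data.frame(values))
    names(expr) <- samples
    expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)

    structure(
      list(expression = expr,
           metadata = tibble::tibble(sample_id = samples, condition = condition),
           truth = list(de_genes = de_genes, block_genes = block_genes,
                        block_pairs = block_pairs)),
      class = "expression_sim"
    )
  })
}

#' Simulate a modular interaction network with planted hubs and bridges
#'
#' Non-hub, non-bridge nodes are split evenly across communities; each
#' community is an internal Erdos-Renyi graph. Bridge nodes attach to at
#' least `ceiling(community_size / 4)` members of every community and are the
#' only inter-community connections apart from hub edges, so they dominate
#' inter-community shortest paths. Hubs then attach to `hub_degree` partners
#' sampled by preferential attachment (probability proportional to current
#' degree + 1). The result is simple: no self-loops, no parallel edges.
#'
#' @param config A [simulation_config()] (only its `network` and `seed`
#'   fields are used).
#' @return A list of class `network_sim` with elements
#'   * `edges`: tibble with columns `gene_1`, `gene_2` (canonical order);
#'   * `nodes`: character vector of all node names (isolates included);
#'   * `truth`: list with `planted_hubs`, `planted_bridges`, `communities`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  net <- config$network
  with_local_seed(config$seed, offset = 1L, {
    n <- net$n_nodes
    nodes <- sprintf("N%05d", seq_len(n))
    hubs <- if (net$n_hubs > 0) sprintf("HUB%03d", seq_len(net$n_hubs)) else character()
    bridges <- if (net$n_bridges > 0) sprintf("BRG%03d", seq_len(net$n_bridges)) else character()
    n_comm_nodes <- n - net$n_hubs - net$n_bridges
    comm_nodes <- sprintf("N%05d", seq_len(n_comm_nodes))
    nodes <- c(comm_nodes, bridges, hubs)
    communities <- split(comm_nodes,
                         rep_len(seq_len(net$n_communities), n_comm_nodes))

    edge_from <- character()
    edge_to <- character()
    add_edges <- function(a, b) {
      edge_from <<- c(edge_from, a)
      edge_to <<- c(edge_to, b)
    }

    # Erdos-Renyi within each community.
    for (members in communities) {
      m <- length(members)
      if (m >= 2) {
        cmb <- utils::combn(members, 2)
        keep <- runif(ncol(cmb)) < net$background_edge_prob
        if (any(keep)) add_edges(cmb[1, keep], cmb[2, keep])
      }
    }

    # Bridges: at least a quarter of every community.
    for (br in bridges) {
      for (members in communities) {
        k <- min(length(members), ceiling(length(members) / 4))
        if (k > 0) add_edges(rep(br, k), sample(members, k))
      }
    }

    # Hubs by preferential attachment over current degrees.
    for (hb in hubs) {
      others <- setdiff(nodes, hb)
      deg <- table(factor(c(edge_from, edge_to), levels = others))
      w <- as.numeric(deg) + 1
      k <- min(net$hub_degree, length(others))
      partners <- sample(others, k, prob = w)
      add_edges(rep(hb, k), partners)
    }

    edges <- order_pairs(tibble::tibble(gene_1 = edge_from, gene_2 = edge_to))
    edges <- dplyr::distinct(dplyr::filter(edges, .data$gene_1 != .data$gene_2))
    edges <- dplyr::arrange(edges, .data$gene_1, .data$gene_2)

    structure(
      list(edges = edges, nodes = nodes,
           truth = list(planted_hubs = hubs, planted_bridges = bridges,
                        communities = communities)),
      class = "network_sim"
    )
  })
}

#' Simulate a full aligned study: expression matrix plus interaction network
#'
#' Runs [simulate_expression()] and [simulate_network()] under one seed and
#' renames the network nodes onto the expression gene symbols (node `i`
#' becomes gene `i`), so the pair can be fed straight into [run_pipeline()].
#' Requires `network$n_nodes == n_genes`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `study_sim` with `expression`, `metadata`,
#'   `edges`, and `truth` (the union of both truth lists; planted hubs and
#'   bridges are reported as gene symbols).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$network$n_nodes != config$n_genes) {
    abort("`network$n_nodes` must equal `n_genes` for an aligned study.")
  }
  es <- simulate_expression(config)
  ns <- simulate_network(config)
  lookup <- setNames(es$expression$gene, ns$nodes)
  edges <- tibble::tibble(gene_1 = unname(lookup[ns$edges$gene_1]),
                          gene_2 = unname(lookup[ns$edges$gene_2]))
  edges <- dplyr::arrange(order_pairs(edges), .data$gene_1, .data$gene_2)
  structure(
    list(expression = es$expression, metadata = es$metadata, edges = edges,
         truth = c(es$truth,
                   list(planted_hubs = unname(lookup[ns$truth$planted_hubs]),
                        planted_bridges = unname(lookup[ns$truth$planted_bridges])))),
    class = "study_sim"
  )
}
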