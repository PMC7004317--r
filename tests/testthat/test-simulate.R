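# Synthetic-data generator: determinism, planted structure, validation.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_control = 2), "n_control")
  expect_error(simulation_config(n_de = 600, n_genes = 500), "n_de")
  expect_error(coexpression_block(10, 1.0), "rho")
  expect_error(coexpression_block(10, -0.1), "rho")
  expect_error(network_config(n_nodes = 50, hub_degree = 50), "hub_degree")
  expect_error(
    simulation_config(blocks = list(coexpression_block(600, 0.5)), n_genes = 500),
    "block_size")
})

test_that("identical seeds give bit-identical expression and networks", {
  cfg <- simulation_config(n_genes = 80, n_de = 10, seed = 99,
                           network = network_config(n_nodes = 60, n_hubs = 2,
                                                    hub_degree = 15))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  na <- simulate_network(cfg)
  nb <- simulate_network(cfg)
  expect_identical(na$edges, nb$edges)
  cfg2 <- simulation_config(n_genes = 80, n_de = 10, seed = 100,
                            network = network_config(n_nodes = 60, n_hubs = 2,
                                                     hub_degree = 15))
  expect_false(identical(simulate_expression(cfg2)$expression, a$expression))
})

test_that("expression matrix has the configured shape and DE mean shifts", {
  cfg <- simulation_config(n_genes = 120, n_control = 10, n_case = 12,
                           n_de = 15, de_shift = 3, noise_sd = 0.2,
                           blocks = list(), seed = 5)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$expression), 120)
  expect_equal(ncol(sim$expression), 1 + 22)
  expect_equal(sum(sim$metadata$condition == "control"), 10)
  em <- as.matrix(sim$expression[-1])
  is_case <- sim$metadata$condition == "case"
  de_idx <- match(sim$truth$de_genes, sim$expression$gene)
  shift <- rowMeans(em[de_idx, is_case]) - rowMeans(em[de_idx, !is_case])
  expect_true(all(abs(shift - 3) < 0.5))
  other <- setdiff(seq_len(120), de_idx)
  shift0 <- rowMeans(em[other, is_case]) - rowMeans(em[other, !is_case])
  expect_true(all(abs(shift0) < 0.5))
})

test_that("planted blocks hit their target correlation; rho = 0 means independence", {
  # Monte-Carlo check of the latent-factor construction over replicates.
  mean_block_r <- function(seed, rho) {
    cfg <- simulation_config(n_genes = 30, n_control = 3, n_case = 100,
                             n_de = 0, noise_sd = 0.5, seed = seed,
                             blocks = list(coexpression_block(10, rho, "case_only")))
    sim <- simulate_expression(cfg)
    em <- as.matrix(sim$expression[-1])
    rownames(em) <- sim$expression$gene
    case_cols <- sim$metadata$condition == "case"
    cm <- cor(t(em[sim$truth$block_genes[[1]], case_cols]))
    mean(cm[upper.tri(cm)])
  }
  r09 <- vapply(1:20, mean_block_r, numeric(1), rho = 0.9)
  expect_true(all(abs(r09 - 0.9) < 0.05))
  r00 <- vapply(1:5, mean_block_r, numeric(1), rho = 0)
  expect_true(all(abs(r00) < 0.15))
})

test_that("case-only blocks are uncorrelated in control samples", {
  cfg <- simulation_config(n_genes = 30, n_control = 100, n_case = 100,
                           n_de = 0, seed = 21,
                           blocks = list(coexpression_block(10, 0.9, "case_only")))
  sim <- simulate_expression(cfg)
  em <- as.matrix(sim$expression[-1])
  rownames(em) <- sim$expression$gene
  ctrl <- sim$metadata$condition == "control"
  cm <- cor(t(em[sim$truth$block_genes[[1]], ctrl]))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.2)
})

test_that("generated networks are simple and community structure is bridged", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed,
                             network = network_config(n_nodes = 80, n_hubs = 2,
                                                      hub_degree = 20,
                                                      n_communities = 2,
                                                      n_bridges = 1,
                                                      background_edge_prob = 0.1))
    ns <- simulate_network(cfg)
    expect_true(all(ns$edges$gene_1 != ns$edges$gene_2))
    expect_false(any(duplicated(paste(ns$edges$gene_1, ns$edges$gene_2))))
    expect_true(all(ns$edges$gene_1 < ns$edges$gene_2))
  }
})

test_that("a single bridge between two dense communities has maximal betweenness", {
  cfg <- simulation_config(seed = 13,
                           network = network_config(n_nodes = 41, n_hubs = 0,
                                                    hub_degree = 5,
                                                    n_communities = 2,
                                                    n_bridges = 1,
                                                    background_edge_prob = 0.6))
  ns <- simulate_network(cfg)
  bc <- betweenness_centrality(ns$edges, ns$nodes)
  expect_equal(names(which.max(bc)), ns$truth$planted_bridges)
})

test_that("hub-free uniform background has binomial-scale degrees", {
  cfg <- simulation_config(seed = 31,
                           network = network_config(n_nodes = 100, n_hubs = 0,
                                                    hub_degree = 5,
                                                    n_communities = 1,
                                                    n_bridges = 0,
                                                    background_edge_prob = 0.1))
  ns <- simulate_network(cfg)
  dc <- degree_centrality(ns$edges, ns$nodes)
  expected <- 99 * 0.1
  expect_lt(abs(mean(dc) - expected), 3 * sqrt(expected))
  expect_true(all(dc < expected + 6 * sqrt(expected * 0.9)))
})
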