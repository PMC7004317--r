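# Network cleaning, centralities, hub and bottleneck calls.

edges_of <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(gene_1 = m[, 1], gene_2 = m[, 2])
}

test_that("cleaning drops self-loops, merges orientations, and is idempotent", {
  raw <- data.frame(a = c("A", "B", "A"), b = c("B", "A", "A"))
  net <- clean_network(raw)
  expect_equal(nrow(net), 1)
  expect_equal(net$gene_1, "A")
  expect_equal(net$gene_2, "B")
  expect_identical(clean_network(net), net)

  simple <- edges_of("A", "B", "B", "C")
  expect_identical(clean_network(simple), simple)
  expect_warning(empty <- clean_network(data.frame(a = character(),
                                                   b = character())), "Empty")
  expect_equal(nrow(empty), 0)
})

test_that("cleaned edge count equals distinct non-loop unordered pairs", {
  set.seed(3)
  syms <- sprintf("N%02d", 1:20)
  raw <- data.frame(a = sample(syms, 100, replace = TRUE),
                    b = sample(syms, 100, replace = TRUE))
  dup_rows <- raw[sample(nrow(raw), 20), ]
  raw <- rbind(raw, dup_rows[, c(1, 2)], setNames(dup_rows[, c(2, 1)], c("a", "b")))
  net <- clean_network(raw)
  key <- unique(ifelse(raw$a < raw$b, paste(raw$a, raw$b), paste(raw$b, raw$a))[raw$a != raw$b])
  expect_equal(nrow(net), length(key))
})

test_that("induced subgraphs keep exactly the edges inside the kept set", {
  tri <- edges_of("A", "B", "A", "C", "B", "C")
  expect_identical(induced_subgraph(tri, c("A", "B", "C")), tri)
  expect_equal(nrow(induced_subgraph(tri, "A")), 0)
  ab <- induced_subgraph(tri, c("A", "B"))
  expect_equal(nrow(ab), 1)
  expect_equal(ab$gene_1, "A")
})

test_that("degree centrality: star, empty graph, handshake lemma", {
  star <- edges_of("C", "L1", "C", "L2", "C", "L3", "C", "L4")
  dc <- degree_centrality(star)
  expect_equal(unname(dc["C"]), 4L)
  expect_true(all(dc[paste0("L", 1:4)] == 1))
  expect_length(degree_centrality(tibble::tibble(gene_1 = character(),
                                                 gene_2 = character())), 0)
  set.seed(8)
  g <- random_graph(15, 0.3)
  expect_equal(sum(degree_centrality(g$edges, g$nodes)), 2 * nrow(g$edges))
})

test_that("betweenness: path center is 1, complete graph is 0, isolates are 0", {
  path3 <- edges_of("A", "B", "B", "C")
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc["B"]), 1)
  expect_equal(unname(bc["A"]), 0)
  k4 <- edges_of("A", "B", "A", "C", "A", "D", "B", "C", "B", "D", "C", "D")
  expect_true(all(betweenness_centrality(k4) == 0))
  expect_warning(bc2 <- betweenness_centrality(edges_of("A", "B")), "3 nodes")
  expect_true(all(bc2 == 0))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  set.seed(17)
  for (i in 1:40) {
    g <- random_graph(sample(4:12, 1), runif(1, 0.2, 0.7))
    impl <- betweenness_centrality(g$edges, g$nodes)
    orc <- oracle_betweenness(g$edges, g$nodes)
    expect_equal(impl[sort(names(impl))], orc[sort(names(orc))],
                 tolerance = 1e-10)
  }
})

test_that("hub cutoff arithmetic and strictness behave as specified", {
  dc <- setNames(c(2, 2, 2, 2, 12), paste0("G", 1:5))
  hc <- classify_hubs(dc)
  expect_equal(hc$cutoff$avg_dc, 4)
  expect_equal(hc$cutoff$sd_dc, sqrt(20))
  expect_equal(hc$cutoff$cutoff, 4 + 2 * sqrt(20))
  expect_length(hc$hubs, 0)

  const <- setNames(rep(3, 6), paste0("G", 1:6))
  expect_length(classify_hubs(const)$hubs, 0)

  pop <- classify_hubs(dc, sd_mode = "population")
  expect_equal(pop$cutoff$sd_dc, sqrt(20 * 4 / 5))

  skewed <- setNames(c(rep(2, 20), 40), paste0("G", 1:21))
  expect_equal(classify_hubs(skewed)$hubs, "G21")
  expect_warning(one <- classify_hubs(setNames(5, "G1")), "Single-node")
  expect_length(one$hubs, 0)
})

test_that("raising the hub multiplier never enlarges the hub set", {
  set.seed(23)
  g <- random_graph(40, 0.15)
  dc <- degree_centrality(g$edges, g$nodes)
  sets <- lapply(c(0, 0.5, 1, 1.5, 2, 3), function(m) classify_hubs(dc, m)$hubs)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("bottleneck quantile call handles zeros, ties, and monotonicity", {
  expect_warning(none <- classify_bottlenecks(setNames(rep(0, 5), paste0("G", 1:5))),
                 "zero")
  expect_length(none, 0)

  bc <- setNames(c(0.9, 0.5, 0.4, 0.1, 0, 0, 0, 0), paste0("G", 1:8))
  expect_equal(classify_bottlenecks(bc, 0.25), c("G1", "G2"))

  tied <- setNames(c(0.9, 0.5, 0.5, 0.1, 0, 0, 0, 0), paste0("G", 1:8))
  expect_equal(classify_bottlenecks(tied, 0.25), c("G1", "G2", "G3"))

  set.seed(29)
  g <- random_graph(30, 0.15)
  bcs <- betweenness_centrality(g$edges, g$nodes)
  sets <- lapply(c(0.1, 0.25, 0.5, 0.9), function(q) classify_bottlenecks(bcs, q))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("centrality_table covers isolated nodes and sorts by degree", {
  edges <- edges_of("A", "B", "B", "C")
  ct <- centrality_table(edges, nodes = c("A", "B", "C", "D"))
  expect_equal(nrow(ct), 4)
  expect_equal(ct$gene[1], "B")
  expect_equal(ct$dc[ct$gene == "D"], 0L)
  expect_equal(ct$bc[ct$gene == "D"], 0)
})
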