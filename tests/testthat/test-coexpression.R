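# Pearson maps, thresholding, contrast, connectivity, prioritization.

test_that("pearson_r matches direct evaluation and handles degeneracy", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(pearson_r(rep(1, 4), 1:4)))
  expect_error(pearson_r(1:4, 1:5), "equal lengths")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation maps are symmetric with unit diagonal and NA for flat genes", {
  set.seed(2)
  m <- matrix(rnorm(10 * 12), nrow = 10)
  m[4, 7:12] <- 2  # flat in case samples only
  d <- make_expr(m, conditions = rep(c("control", "case"), each = 6))
  expect_warning(cmap <- correlation_map(d$expr, d$meta, "case"), "zero variance")
  expect_equal(cmap$r, t(cmap$r))
  defined <- setdiff(seq_len(10), 4)
  expect_true(all(diag(cmap$r)[defined] == 1))
  expect_true(all(is.na(cmap$r[4, ])))
  # same gene is fine in the control samples
  ctrl <- correlation_map(d$expr, d$meta, "control")
  expect_false(anyNA(ctrl$r))
  # genes absent from the matrix are skipped with a warning
  expect_warning(small <- correlation_map(d$expr, d$meta, "control",
                                          genes = c("G1", "G2", "NOPE")),
                 "absent")
  expect_equal(small$genes, c("G1", "G2"))
})

test_that("identical replicated samples yield all-missing correlations", {
  m <- matrix(rep(1:5, 8), nrow = 5)
  d <- make_expr(m, conditions = rep(c("control", "case"), each = 4))
  expect_warning(cmap <- correlation_map(d$expr, d$meta, "case"), "zero variance")
  expect_true(all(is.na(cmap$r)))
})

test_that("tidy() of a correlation map lists each unordered pair once", {
  set.seed(4)
  d <- make_expr(matrix(rnorm(6 * 8), nrow = 6),
                 conditions = rep(c("control", "case"), each = 4))
  cmap <- correlation_map(d$expr, d$meta, "case")
  long <- tidy(cmap)
  expect_equal(nrow(long), choose(6, 2))
  expect_true(all(long$gene_1 < long$gene_2))
})

test_that("thresholding is monotone, boundary-exact and never passes NA", {
  set.seed(5)
  d <- make_expr(matrix(rnorm(8 * 10), nrow = 8),
                 conditions = rep(c("control", "case"), each = 5))
  cmap <- correlation_map(d$expr, d$meta, "case")
  e1 <- threshold_network(cmap, 0.3)
  e2 <- threshold_network(cmap, 0.6)
  expect_true(all(paste(e2$gene_1, e2$gene_2) %in% paste(e1$gene_1, e1$gene_2)))
  expect_true(all(e1$r >= 0.3))
  perfect <- threshold_network(cmap, 1.0)
  expect_equal(nrow(perfect), 0)
  abs_edges <- threshold_network(cmap, 0.6, sign = "absolute")
  expect_true(all(abs(abs_edges$r) >= 0.6))
  expect_gte(nrow(abs_edges), nrow(e2))
})

test_that("null data produce essentially no r >= 0.8 pairs at n = 100", {
  cfg <- simulation_config(n_genes = 60, n_control = 3, n_case = 100,
                           n_de = 0, blocks = list(), seed = 77)
  sim <- simulate_expression(cfg)
  cmap <- correlation_map(sim$expression, sim$metadata, "case")
  edges <- threshold_network(cmap, 0.8)
  expect_lte(nrow(edges), ceiling(0.001 * choose(60, 2)))
})

test_that("contrast attaches control correlations and flags missing pairs", {
  set.seed(6)
  d <- make_expr(matrix(rnorm(6 * 10), nrow = 6),
                 conditions = rep(c("control", "case"), each = 5))
  case_map <- correlation_map(d$expr, d$meta, "case")
  ctrl_map <- correlation_map(d$expr, d$meta, "control")
  edges <- threshold_network(case_map, 0.1)
  ctr <- contrast_conditions(edges, ctrl_map)
  expect_s3_class(ctr, "coexpr_contrast")
  expect_equal(nrow(ctr), nrow(edges))
  i <- 1
  expect_equal(ctr$r_control[i],
               ctrl_map$r[ctr$gene_1[i], ctr$gene_2[i]])
  # empty disease edge list -> empty contrast
  empty <- contrast_conditions(edges[0, ], ctrl_map)
  expect_equal(nrow(empty), 0)
  # pair outside the control map -> NA with warning
  small_ctrl <- correlation_map(d$expr, d$meta, "control", genes = c("G1", "G2"))
  expect_warning(part <- contrast_conditions(edges, small_ctrl), "missing")
  expect_true(anyNA(part$r_control))
})

test_that("contrast tables round-trip through TSV at 4-decimal precision", {
  pairs <- adipose_coexpression_pairs()
  ctr <- tibble::tibble(gene_1 = pairs$gene_1, gene_2 = pairs$gene_2,
                        r_disease = pairs$r_obese, r_control = pairs$r_normal)
  class(ctr) <- c("coexpr_contrast", class(ctr))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast(ctr, path)
  back <- read_contrast(path)
  expect_equal(back$r_disease, ctr$r_disease, tolerance = 1e-9)
  expect_equal(back$r_control, ctr$r_control, tolerance = 1e-9)
  expect_equal(back$gene_1, ctr$gene_1)
})

test_that("connectivity counts reproduce the published candidate tallies", {
  pairs <- adipose_coexpression_pairs()
  cc <- connectivity_counts(pairs, unreported_ssgs())
  counts <- setNames(cc$connectivity, cc$gene)
  expect_equal(unname(counts["ENPEP"]), 21L)
  expect_equal(unname(counts["WNK1"]), 20L)
  expect_equal(unname(counts["CYP3A5"]), 6L)
  expect_equal(unname(counts["CTSA"]), 3L)
  expect_equal(unname(counts["SLC24A3"]), 3L)
  absent <- connectivity_counts(pairs, "NOTAGENE")
  expect_equal(absent$connectivity, 0L)
  empty <- connectivity_counts(pairs[0, ], c("ENPEP", "WNK1"))
  expect_true(all(empty$connectivity == 0))
})

test_that("reported/unreported classification follows the annotation set", {
  st <- adipose_ssg_status()
  annotation <- st$gene[st$role == "reported"]
  cls <- classify_reported(st$gene, annotation)
  expect_equal(sum(!cls$reported), 8)
  expect_setequal(cls$gene[!cls$reported], unreported_ssgs())
  all_un <- classify_reported(c("A", "B"), character())
  expect_false(any(all_un$reported))
  all_rep <- classify_reported(c("A", "B"), c("A", "B", "C"))
  expect_true(all(all_rep$reported))
})

test_that("prioritization selects unreported genes above the connectivity floor", {
  pairs <- adipose_coexpression_pairs()
  cc <- connectivity_counts(pairs, unreported_ssgs())
  cls <- classify_reported(unreported_ssgs(), character())
  pr <- prioritize_candidates(cc, cls, min_connectivity = 3)
  expect_setequal(pr$gene[pr$selected],
                  c("ENPEP", "WNK1", "CYP3A5", "SLC24A3", "CTSA"))
  # ranked by connectivity descending, alphabetical on ties
  expect_equal(pr$gene[1:2], c("ENPEP", "WNK1"))
  expect_equal(pr$gene[4:5], c("CTSA", "SLC24A3"))
  expect_true(all(prioritize_candidates(cc, cls, 0)$selected))
  expect_false(any(prioritize_candidates(cc, cls, 100)$selected))
  # reported genes are never selected regardless of connectivity
  rep_cls <- classify_reported(unreported_ssgs(), "ENPEP")
  pr2 <- prioritize_candidates(cc, rep_cls, 3)
  expect_false(pr2$selected[pr2$gene == "ENPEP"])
})
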