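---
title: "Tracing salt-sensitivity genes in adipose expression data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing salt-sensitivity genes in adipose expression data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspin)
library(dplyr)
```

## The problem and the model

Salt sensitivity — the coupling of blood pressure to dietary salt — is
mediated by a comparatively small set of genes (the renin–angiotensin–
aldosterone pathway plus literature-curated additions), and several of them
are expressed in adipose tissue. `sspin` implements an integrated
network-biology pipeline that asks which of these salt-sensitivity genes
(SSGs) sit at influential positions in the interaction network of genes
differentially expressed in obese versus lean visceral adipose tissue, and
which of them co-express with disease genes only in the disease state. The
pipeline is a chain of simple, auditable rules rather than one joint model;
each stage is exposed as a function and the chain as `run_pipeline()`.

The stages, with their parameters:

1. **Differential expression** (`deg_test()`, `select_degs()`). Per gene, an
   unpaired two-sample t-test between conditions on the log2 matrix,
   two-sided, pooled-variance by default (`welch = TRUE` switches to the
   unequal-variance form). P-values are Benjamini–Hochberg adjusted and
   genes with adjusted p ≤ α = 0.05 are kept. The significance convention
   here is deliberately configurable: "FDR … with a p value of 0.05" can be
   read as thresholding either raw or adjusted p-values, and we default to
   the adjusted reading (the stricter and more standard one), with
   `use_adjusted = FALSE` available.
2. **Interaction network** (`clean_network()`, `induced_subgraph()`).
   Interaction exports are reduced to a simple undirected graph — self-loops
   dropped, orientations merged, duplicates removed — and restricted to the
   DEGs. Cleaning is idempotent.
3. **Centrality** (`centrality_table()`). Degree centrality DC(v) counts
   interaction partners. Betweenness centrality is
   BC(v) = Σ_{s≠v≠t} σ_st(v)/σ_st over unordered pairs, normalized by
   (n−1)(n−2)/2 so that BC ∈ [0, 1]. Brandes' accumulation (via igraph)
   does the computation; the test suite holds it equal to an exhaustive
   shortest-path enumeration oracle on hundreds of small random graphs.
4. **Hubs** (`classify_hubs()`). A node is a hub when
   DC > mean(DC) + 2·SD(DC), computed over all nodes of the analyzed
   network. The multiplier and the SD flavour (sample vs population) are
   parameters; sample SD is the default since the hub-cutoff convention in
   the literature does not specify the divisor.
5. **Bottlenecks** (`classify_bottlenecks()`). Nodes in the top quartile of
   the betweenness distribution (`quantile = 0.25` of all nodes, ranked
   descending).
6. **HBS and the SS-PIN** (`assemble_hbs()`, `extract_sspin()`). The union
   of hubs, bottlenecks and SSGs, with full inclusion–exclusion accounting,
   and the subgraph of the PIN induced on that union.
7. **Differential co-expression** (`correlation_map()`,
   `threshold_network()`, `contrast_conditions()`). Pearson correlation of
   every unordered gene pair of the SS-PIN panel, separately per condition.
   Disease pairs with r ≥ 0.8 form the disease co-expression network; each
   disease edge is annotated with the same pair's control correlation. Only
   positive correlations are screened by default (`sign = "positive"`),
   matching the high-positive-correlation rationale of the analysis;
   `"absolute"` is available for exploration.
8. **Prioritization** (`connectivity_counts()`, `classify_reported()`,
   `prioritize_candidates()`). SSGs present in the contrast are classified
   reported/unreported against a disease annotation set; unreported genes
   with at least `min_connectivity = 3` co-expression partners are selected,
   ranked by connectivity with alphabetical tie-break.
9. **Enrichment** (`hypergeom_enrich()`). A one-sided hypergeometric
   over-representation test with BH correction over user-supplied GMT
   libraries. The original analysis used a proprietary web-service
   annotation corpus for this stage; the package provides the standard
   offline equivalent so the stage is reproducible and testable against an
   exact combinatorial oracle. Enrichment p-values therefore depend
   entirely on the library the user supplies.

## Choices where the procedure was genuinely open

* **Hub strictness.** The cutoff comparison is strict (`DC > cutoff`), so a
  degenerate network where every degree is equal calls no hubs rather than
  all of them.
* **Bottleneck ties and zeros.** The top-quartile cut takes
  `ceiling(0.25·n)` nodes and extends across ties at the boundary value, so
  the call never depends on input order. Nodes with BC = 0 are never called
  bottlenecks: they lie on no shortest path, and a quantile rule that
  swept them in on a zero boundary tie would make the "bottleneck" label
  vacuous.
* **Disconnected graphs.** Betweenness is accumulated within components but
  normalized by the global pair count, keeping values comparable across one
  analysis.
* **The 502-of-2691 question.** The source analysis reports 502 bottlenecks
  from 2691 genes, which is not a literal 25% of all nodes (673). The basis
  set it used is unstated; we take all nodes at quantile 0.25 and do not
  attempt to force that count.
* **Degenerate variance in the t-test.** A gene flat in both groups with
  equal means is a clean null (t = 0, p = 1). Flat with unequal means is
  perfect separation; p is recorded as 0 with a warning rather than NA, so
  such genes are retained and flagged instead of silently vanishing.
* **Zero-variance genes in correlation maps.** Their correlations are
  undefined and recorded as missing (never 0); missing never crosses the
  co-expression threshold.
* **SSGs absent from the network.** They stay in the SSG label set for the
  HBS union but are reported separately as unmapped, since a gene can be a
  curated SSG without being differentially expressed.
* **The 5-gene shortlist rule.** The published narrowing of 8 unreported
  SSGs to 5 was described only as "co-expression and topological
  parameters". A minimum of 3 co-expression partners reproduces the
  published shortlist from the published contrast table, and is exposed as
  `min_connectivity` rather than hard-coded, since it is a modeling choice.
* **t-statistic sign.** `t = (mean_case − mean_control)/SE`; only two-sided
  p-values are consumed downstream, so the convention is cosmetic.

## The synthetic-data generator

`simulate_expression()` and `simulate_network()` (and their aligned wrapper
`simulate_study()`) generate data with exactly the statistical structure the
pipeline assumes, plus ground-truth labels, so every stage can be tested for
*recovery* rather than merely for running.

* **Design.** Defaults mirror the motivating study's design: 14 control and
  16 case samples, log2 scale. Each gene has a constant baseline drawn once
  from N(8, 2) — the typical location and spread of log2 microarray
  intensities — plus N(0, 0.5²) noise. Fifty planted DE genes get a
  2-log2-unit case shift; with n = 14 + 16 and σ = 0.5 that corresponds to
  a very well-powered effect, which is what a DEG stage feeding a network
  analysis presumes.
* **Co-expression blocks.** A block of genes shares a per-sample latent
  factor in its active condition: value = √ρ·f_s + √(1−ρ)·ε, giving
  expected pairwise correlation exactly ρ at O(block size) cost (a Cholesky
  factor of the full block correlation matrix would give the same law at
  more cost). The default single case-only block of 10 genes at ρ = 0.9
  is the disease-specific signal the contrast stage is designed to find.
* **Network.** 300 nodes: 3 Erdős–Rényi communities (p = 0.05) connected
  only through 2 bridge nodes that attach to a quarter of every community,
  plus 5 hubs wired to ~60 partners by preferential attachment — roughly
  ten times the background degree, matching the "planted hub" regime the
  recovery tests quantify. Bridges are guaranteed high betweenness by
  construction without disconnecting the graph.
* **Determinism.** One integer seed governs everything; per-component
  sub-streams are derived from it, and equal configurations give
  bit-identical matrices and edge sets.

What the generator does **not** emulate: probe-level effects, batch
structure, heteroskedastic noise, negative correlation blocks, RNA-seq
counts, and the literature bias of curated interaction databases. Passing
recovery tests on this generator therefore demonstrates the pipeline's
correctness on data satisfying its own assumptions, not robustness to the
artefacts of real microarray or interactome data.

## Bundled study tables

Five small TSVs transcribed from the published analysis (top-centrality
genes; the 15 SSG–bottleneck overlaps; the 123-gene obesity annotation
partition; the 23 co-expressed SSGs with reported/unreported status; the 56
disease co-expression pairs of the unreported SSGs with obese and lean
correlations) are shipped under `inst/extdata/` with accessors
`adipose_*()`. They let the downstream stages run and be verified without
the original expression data, which is not redistributable at package
scale. The full-data results of the original study (2691 DEGs, 40 hubs, 502
bottlenecks, the 226-gene co-expression network) depend on that data and on
commercial-scale interaction databases and are not reproduced here.

## Problem sizes in the test suite

The suite checks oracle equivalence of betweenness on random graphs of up to
12 nodes (hundreds of them — exhaustive path enumeration is exponential, and
a dozen nodes is where the oracle stays instant while still covering every
interesting topology), hub/bridge recovery on the default 300-node
generator over 10 seeds, co-expression block recovery at 100 + 100 samples
over 20 seeds (100 samples puts the null tail of r̂ far below the 0.8
threshold, so recovery is a sharp test), and null DEG rates on 300-gene
matrices over 20 seeds. These sizes were chosen as the smallest at which
each property is sharply testable; the functions themselves have no
size-specific logic.

## A worked run

```{r pipeline-run}
cfg <- simulation_config(
  n_genes = 120, n_de = 40,
  blocks = list(coexpression_block(8, 0.9, "case_only")),
  network = network_config(n_nodes = 120, n_hubs = 3, hub_degree = 30),
  seed = 11)
study <- simulate_study(cfg)
ssgs <- c(study$truth$block_genes[[1]], study$truth$de_genes[1:5])
run <- run_pipeline(study$expression, study$metadata, study$edges,
                    ssgs = ssgs, config = pipeline_config(alpha = 1))
glance(run)
tidy(run) |> filter(selected)
```

The fixture-driven path needs no simulation at all:

```{r fixtures}
pairs <- adipose_coexpression_pairs()
status <- adipose_ssg_status()
cc <- connectivity_counts(pairs, status$gene[status$role == "unreported"])
prioritize_candidates(cc, classify_reported(cc$gene, character()),
                      min_connectivity = 3)
```

## Known limitations

* The co-expression screen is a plain threshold on r; no differential
  correlation test (e.g. Fisher z) is applied, mirroring the source
  procedure. Pairs near the threshold are sensitive to single samples at
  n = 14/16.
* Betweenness on very large PINs is O(VE); the package targets
  thousands-of-nodes networks, not whole interactomes with millions of
  edges.
* The hypergeometric enrichment is only as meaningful as the supplied GMT
  library and universe; the default universe (network nodes) is the
  conservative choice for network-derived queries.
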