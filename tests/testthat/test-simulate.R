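test_that("identical configs yield byte-identical outputs", {
  cfg <- small_sim_config(seed = 3, n_genes = 200L, sizes = rep(30L, 4L))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$expression$T$counts, s2$expression$T$counts)
  expect_identical(unclass(s1$regulators), unclass(s2$regulators))
  expect_identical(s1$lists, s2$lists)
})

test_that("degenerate edge probabilities give cliques and no inter edges", {
  cfg <- sim_config(
    n_genes = 6L, module_sizes = c(3L, 3L), tissues = "T",
    tissue_modules = list(T = 1:2), n_case = c(T = 3L), n_control = c(T = 3L),
    intra_edge_p = 1, inter_edge_p = 0, decoy_fraction = 0,
    regulator_counts = c(TF = 1L, miRNA = 1L, lncRNA = 1L),
    n_pivots = c(TF = 0L, miRNA = 0L, lncRNA = 0L), targeting_odds = 1,
    risk_list_size = c(sfari = 2L, dvmt = 2L),
    risk_modules = list(sfari = 1L, dvmt = 2L), tissue_list_size = 3L,
    tissue_specific_modules = list(T = integer(0)),
    crosstalk_pairs = list(), seed = 1)
  net <- simulate_ppi_network(cfg)
  blocks <- net$truth$module_membership
  expect_equal(nrow(net$edges), 6L)  # two 3-cliques
  same_block <- blocks[net$edges$protein1] == blocks[net$edges$protein2]
  expect_true(all(same_block))
  expect_true(all(net$edges$combined_score >= 900))
})

test_that("edge count matches the binomial expectation within 3 SD", {
  cfg <- small_sim_config(seed = 1, decoy_fraction = 0)
  net <- simulate_ppi_network(cfg)
  n_intra_pairs <- 5 * choose(60, 2)
  n_inter_pairs <- choose(600, 2) - n_intra_pairs
  mu <- 0.3 * n_intra_pairs + 0.01 * n_inter_pairs
  sdv <- sqrt(0.3 * 0.7 * n_intra_pairs + 0.01 * 0.99 * n_inter_pairs)
  expect_lt(abs(nrow(net$edges) - mu), 3 * sdv)
  # no self-loops or duplicate unordered pairs
  expect_true(all(net$edges$protein1 != net$edges$protein2))
  key <- paste(pmin(net$edges$protein1, net$edges$protein2),
               pmax(net$edges$protein1, net$edges$protein2))
  expect_false(any(duplicated(key)))
})

test_that("planted partition is assortative (positive modularity)", {
  cfg <- small_sim_config(seed = 2, decoy_fraction = 0)
  net <- simulate_ppi_network(cfg)
  blocks <- net$truth$module_membership[igraph::V(net$network)$name]
  q <- igraph::modularity(net$network, blocks + 1L)
  expect_gt(q, 0)
})

test_that("count matrices are integer, non-negative, with no all-zero sample", {
  cfg <- small_sim_config(seed = 4, n_genes = 200L, sizes = rep(30L, 4L))
  sim <- simulate_expression(plant_truth(cfg), cfg, "T")
  expect_true(is.integer(sim$counts))
  expect_true(all(sim$counts >= 0))
  expect_true(all(colSums(sim$counts) > 0))
  expect_identical(colnames(sim$counts), sim$samples$sample_id)
})

test_that("no planted structure means near-zero within-module correlation", {
  cfg <- small_sim_config(seed = 5, module_loading = 0, de_log2fc = 0,
                          n_case = 12L, n_control = 12L)
  sim <- simulate_expression(plant_truth(cfg), cfg, "T")
  x <- log2(normalize_counts(sim$counts) + 1)
  blocks <- plant_truth(cfg)$module_membership
  mem <- names(blocks)[blocks == 1]
  cm <- cor(t(x[mem, ]))
  vals <- cm[upper.tri(cm)]
  expect_gt(length(vals), 1000)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("module loading separates within- from between-module correlation", {
  cfg <- small_sim_config(seed = 6, module_loading = 0.9)
  truth <- plant_truth(cfg)
  sim <- simulate_expression(truth, cfg, "T")
  x <- log2(normalize_counts(sim$counts) + 1)
  blocks <- truth$module_membership
  m1 <- names(blocks)[blocks == 1]; m2 <- names(blocks)[blocks == 2]
  within <- cor(t(x[m1, ]))
  between <- cor(t(x[m1, ]), t(x[m2, ]))
  expect_gt(median(abs(within[upper.tri(within)])), median(abs(between)))
})

test_that("planted DE genes shift group mean ratios as designed", {
  # planted |log2FC| = 1 should put the normalized case/control ratio in
  # [1.5, 2.7] for >= 90% of planted genes across seeds
  hits <- 0; tot <- 0
  for (s in 1:10) {
    sim <- simulate_de_counts(n_genes = 400, n_de = 100, log2fc = 1,
                              dispersion = 0.15, seed = s)
    q <- normalize_counts(sim$counts)
    case <- sim$samples$condition == "case"
    ratio <- rowMeans(q[sim$de_genes, case]) / rowMeans(q[sim$de_genes, !case])
    ratio <- ifelse(ratio < 1, 1 / ratio, ratio)
    hits <- hits + sum(ratio >= 1.5 & ratio <= 2.7)
    tot <- tot + length(ratio)
  }
  # target probability 0.9, allowing two Monte-Carlo standard errors
  expect_gte(hits / tot, 0.9 - 2 * sqrt(0.9 * 0.1 / tot))
})

test_that("regulator maps respect pivot guarantees and null settings", {
  cfg <- small_sim_config(seed = 7)
  truth <- plant_truth(cfg)
  regs <- simulate_regulators(truth, cfg)
  expect_setequal(names(attr(regs, "description")), names(regs))
  blocks <- truth$module_membership
  piv <- truth$pivot_regulators
  expect_gt(nrow(piv), 0)
  for (i in seq_len(nrow(piv))) {
    in_mod <- sum(blocks[regs[[piv$regulator[i]]]] == piv$module[i])
    expect_gte(in_mod, 2)
    # odds-20 targeting of a 60-gene block in a 600-gene universe:
    # expectation ~ 50 * 1200/1740 >> 5 (the uniform expectation)
    expect_gt(in_mod, 5)
  }
  # targeting_odds = 1 plants no pivots at all
  cfg0 <- small_sim_config(seed = 7, targeting_odds = 1)
  expect_equal(nrow(plant_truth(cfg0)$pivot_regulators), 0)
})

test_that("risk lists are enriched in their designated blocks", {
  cfg <- small_sim_config(seed = 8)
  truth <- plant_truth(cfg)
  lists <- simulate_gene_lists(truth, cfg)
  blocks <- truth$module_membership
  k <- sum(blocks[lists$sfari] == 1)
  uniform_expectation <- length(lists$sfari) * 60 / 600
  expect_gt(k, 5 * uniform_expectation / 2)  # strongly above uniform
  # odds 1 with no designated blocks: flat sampling over the universe
  cfg0 <- small_sim_config(seed = 8, risk_odds = 1)
  l0 <- simulate_gene_lists(plant_truth(cfg0), cfg0)
  expect_equal(length(l0$sfari), 60)
})

test_that("invalid configurations are rejected", {
  expect_error(small_sim_config(seed = 1, n_genes = 100L),
               "exceeds n_genes")
  expect_error(small_sim_config(seed = 1, intra_edge_p = 0.01,
                                inter_edge_p = 0.3), "assortative")
  expect_error(small_sim_config(seed = 1, intra_edge_p = 2), "intra_edge_p")
})

test_that("simulate_study writes a complete, re-readable file bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 9, n_genes = 200L, sizes = rep(30L, 4L))
  study <- simulate_study(cfg, dir = dir)
  counts <- read_counts(study$paths$counts_T)
  expect_identical(counts, `storage.mode<-`(study$expression$T$counts, "double"))
  net <- read_edges(study$paths$network)
  expect_equal(igraph::ecount(net), nrow(study$edges))
  regs <- read_gmt(study$paths$regulators)
  expect_identical(sort(names(regs)), sort(names(study$regulators)))
  expect_identical(sort(read_gene_list(study$paths$sfari)),
                   sort(study$lists$sfari))
})
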