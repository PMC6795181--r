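test_that("hypergeometric tails match enumeration on small universes", {
  expect_equal(hypergeom_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hyper_tail_enum(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  # forced overlap in a degenerate universe
  expect_equal(hypergeom_tail(6, 6, 6, 6), 1)
  expect_error(hypergeom_tail(3, 12, 5, 10), "margins")
  expect_error(hypergeom_tail(6, 4, 5, 10), "overlap")
})

test_that("larger overlaps never receive larger p-values", {
  for (k in 1:5) {
    expect_lte(hypergeom_tail(k + 1, 8, 6, 30), hypergeom_tail(k, 8, 6, 30))
  }
})

test_that("BH adjustment follows the step-up rule and handles NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  # monotone after sorting by raw p
  set.seed(14)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("module-list enrichment uses the module-eligible universe", {
  universe <- sprintf("g%03d", 1:100)
  assign <- setNames(c(rep(1L, 20), rep(2L, 30), rep(0L, 50)), universe)
  glist <- universe[1:15]  # all inside module 1
  res <- module_list_enrichment(assign, glist, universe)
  expect_equal(res$module, c(1L, 2L))
  expect_equal(res$k[1], 15)
  expect_equal(res$K, c(15L, 15L))
  expect_equal(res$N, c(100L, 100L))
  expect_equal(res$p[1], hypergeom_tail(15, 15, 20, 100))
  expect_equal(res$padj, bh_adjust(res$p))
  # a module equal to the whole universe is never enriched
  all_one <- setNames(rep(1L, 100), universe)
  expect_equal(module_list_enrichment(all_one, glist, universe)$p, 1)
  expect_error(module_list_enrichment(assign, c("zz1", "zz2"), universe),
               "no overlap")
})

test_that("planted risk lists rank their designated module first", {
  hits <- 0
  for (s in 1:20) {
    cfg <- small_sim_config(seed = 100 + s)
    truth <- plant_truth(cfg)
    lists <- simulate_gene_lists(truth, cfg)
    res <- module_list_enrichment(truth$module_membership, lists$sfari,
                                  truth$genes)
    if (res$module[which.min(res$p)] == 1L) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("candidate modules must contain DEGs and stay under the size cap", {
  genes <- sprintf("g%04d", 1:800)
  assign <- setNames(c(rep(1L, 500), rep(2L, 30), rep(3L, 30)), genes[1:560])
  degs <- c(genes[1], genes[501])  # in modules 1 and 2
  expect_equal(select_candidate_modules(assign, degs), 2L)   # 500 excluded
  expect_equal(select_candidate_modules(assign, degs, max_size = 501L),
               c(1L, 2L))
  expect_equal(select_candidate_modules(assign, character(0)), integer(0))
})

test_that("dysfunctional flags follow single-list significance", {
  es <- data.frame(module = 1:3, p = c(0.04, 0.3, 0.05))
  ed <- data.frame(module = 1:3, p = c(0.3, 0.2, 0.049))
  dys <- flag_dysfunctional(es, ed, alpha = 0.05)
  expect_equal(dys$dysfunctional, c(TRUE, FALSE, TRUE))
  expect_equal(dys$sfari_significant, c(TRUE, FALSE, FALSE))  # 0.05 strict
  expect_equal(dys$dvmt_significant, c(FALSE, FALSE, TRUE))
})

test_that("ORA against a GMT collection reduces to the hypergeometric test", {
  universe <- sprintf("g%03d", 1:40)
  collection <- list(set_a = universe[1:20], set_b = universe[21:40])
  res <- ora_gmt(universe[1:20], collection, universe, verbose = FALSE)
  # the fully-hit set attains the minimum possible p for its margins
  expect_equal(res$p[res$set == "set_a"], hypergeom_tail(20, 20, 20, 40))
  expect_equal(min(res$p), res$p[res$set == "set_a"])
  # disjoint lists are uniformly null
  res0 <- ora_gmt(universe[21:25], list(s = universe[1:10]), universe,
                  verbose = FALSE)
  expect_equal(res0$p, 1)
  # duplicates are deduplicated; singleton collections match the primitive
  res1 <- ora_gmt(rep(universe[1:5], 3), list(s = universe[1:10]), universe,
                  verbose = FALSE)
  expect_equal(res1$p, hypergeom_tail(5, 10, 5, 40))
  expect_equal(res1$padj, res1$p)
})

test_that("pivot calls require both the target count and the enrichment", {
  universe <- sprintf("g%03d", 1:100)
  assign <- setNames(c(rep(1L, 20), rep(2L, 20), rep(0L, 60)), universe)
  regmap <- list(
    one_strong = universe[1],           # k = 1 however small p would be
    two_weak = c(universe[1:2], universe[41:88]),  # k = 2 but diluted
    focused = universe[1:10])           # k = 10 of K = 10
  attr(regmap, "description") <- c(one_strong = "TF", two_weak = "miRNA",
                                   focused = "lncRNA")
  res <- pivot_regulators(regmap, assign, c(1L, 2L), universe)
  r1 <- res[res$regulator == "one_strong" & res$module == 1, ]
  expect_equal(r1$k, 1)
  expect_false(r1$is_pivot)
  r2 <- res[res$regulator == "two_weak" & res$module == 1, ]
  expect_equal(r2$k, 2)
  expect_gt(r2$p, 0.05)
  expect_false(r2$is_pivot)
  r3 <- res[res$regulator == "focused" & res$module == 1, ]
  expect_true(r3$is_pivot)
  expect_equal(r3$p, hypergeom_tail(10, 10, 20, 100))
  # a regulator with exactly one target in every module is never flagged
  spread <- list(spread = c(universe[1], universe[21]))
  attr(spread, "description") <- c(spread = "TF")
  res_s <- pivot_regulators(spread, assign, c(1L, 2L), universe)
  expect_false(any(res_s$is_pivot))
})

test_that("restricting pivot targets to DEGs changes the tested sets", {
  universe <- sprintf("g%03d", 1:60)
  assign <- setNames(c(rep(1L, 20), rep(0L, 40)), universe)
  regmap <- list(r = universe[1:10])
  attr(regmap, "description") <- c(r = "TF")
  full <- pivot_regulators(regmap, assign, 1L, universe)
  degs_only <- pivot_regulators(regmap, assign, 1L, universe,
                                degs = universe[1:2])
  expect_equal(full$k, 10)
  expect_equal(degs_only$k, 2)
  expect_equal(degs_only$K, 2)
})
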