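test_that("the expression transform drops constant genes and respects depth", {
  set.seed(6)
  # a large block of flat anchor genes pins every size factor at exactly 1
  anchors <- matrix(50L, nrow = 101, ncol = 6)
  noisy <- matrix(rnbinom(20 * 6, mu = 100, size = 8) + 1L, nrow = 20)
  counts <- rbind(anchors, noisy)
  dimnames(counts) <- list(sprintf("g%03d", 1:121), paste0("s", 1:6))
  expect_equal(unname(size_factors(counts)), rep(1, 6))
  x <- expression_transform(counts, verbose = FALSE)
  # normalized anchor genes are constant, hence dropped
  expect_false(any(sprintf("g%03d", 1:101) %in% rownames(x)))
  expect_equal(nrow(x), 20)
  # doubling one sample is absorbed into the size factors up to the global
  # depth remainder 2^(1/n_ref) that the within-matrix geometric means take
  doubled <- counts
  doubled[, 2] <- counts[, 2] * 2L
  x2 <- expression_transform(doubled, verbose = FALSE)
  expect_lt(max(abs(x2 - x)), log2(2^(1 / 6)) + 0.01)
  expect_lt(max(abs(cor(t(x2)) - cor(t(x)))), 1e-3)
})

test_that("adjacency is the soft-thresholded absolute correlation", {
  set.seed(7)
  expr <- matrix(rnorm(10 * 6), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  a <- adjacency_matrix(expr, power = 7)
  oracle <- abs(cor(t(expr)))^7
  diag(oracle) <- 0
  expect_equal(a, oracle, tolerance = 1e-12)
  expect_true(all(diag(a) == 0))
  expect_error(adjacency_matrix(expr[, 1:2], 6), "3 samples")
  expect_error(adjacency_matrix(expr, 0.5), "power")
})

test_that("scale-free fit is high for power-law connectivity, zero when flat", {
  # expected-degree (Chung-Lu style) weighted graph with power-law degrees
  n <- 400
  k <- 4 * (1:n)^(-0.5)
  w <- outer(k, k) / sum(k)
  diag(w) <- 0
  dimnames(w) <- list(paste0("g", 1:n), paste0("g", 1:n))
  expect_gte(scale_free_fit(w), 0.95)
  set.seed(8)
  perm <- sample(n)
  expect_equal(scale_free_fit(w[perm, perm]), scale_free_fit(w))
  flat <- matrix(0.4, 30, 30); diag(flat) <- 0
  expect_warning(r2 <- scale_free_fit(flat), "degenerate")
  expect_equal(r2, 0)
})

test_that("topological overlap matches the hand case and the cubic oracle", {
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  tom <- tom_similarity(tri)
  expect_equal(tom[1, 2], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(diag(tom), rep(1, 3))

  iso <- matrix(0, 2, 2)
  expect_equal(tom_similarity(iso)[1, 2], 0)

  set.seed(9)
  for (r in 1:5) {
    a <- matrix(runif(20 * 20, 0, 0.9), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-10)
  }
})

test_that("average-linkage dendrograms behave on constructed fixtures", {
  # two perfectly similar pairs, dissimilar across pairs
  d <- matrix(1, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.05
  d[3, 4] <- d[4, 3] <- 0.08
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:4), paste0("g", 1:4))
  h <- cluster_dendrogram(d)
  expect_equal(sort(h$height[1:2]), c(0.05, 0.08))
  expect_true(all(diff(h$height) >= -1e-12))  # monotone heights
  # identical rows merge at ~0 height
  d0 <- matrix(0.9, 3, 3); diag(d0) <- 0
  d0[1, 2] <- d0[2, 1] <- 0
  expect_equal(min(cluster_dendrogram(d0)$height), 0)
  expect_error(cluster_dendrogram(matrix(0, 1, 1)), "2 genes")
})

test_that("static cuts respect the minimum module size", {
  d <- matrix(0.999, 30, 30); diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:30), paste0("g", 1:30))
  h <- cluster_dendrogram(d)
  expect_true(all(cut_modules(h, 20, 0.5) == 0))       # nothing coheres
  expect_true(all(cut_modules(h, 31, 0.9999) == 0))    # min size above n
  expect_error(cut_modules(h, 20, 1.5), "cut_height")
})

test_that("eigengenes are unit-norm, sign-oriented, and PCA-optimal", {
  expr <- make_two_module_expr(0.3)
  assign <- setNames(rep(c(1L, 2L), each = 25), rownames(expr))
  me <- module_eigengenes(expr, assign)
  expect_equal(colnames(me), c("ME1", "ME2"))
  expect_equal(unname(colSums(me^2)), c(1, 1), tolerance = 1e-12)
  # rank-1 module: all members correlate perfectly with the eigengene
  kme <- kme_and_hubs(expr, assign, me)
  expect_equal(kme$kme, rep(1, 50), tolerance = 1e-9)
  expect_true(all(kme$is_hub))
  # canonical orientation: mean member correlation is non-negative, so
  # negating the input rows flips nothing observable
  me_flip <- module_eigengenes(-expr, assign)
  expect_gte(mean(cor(me_flip[, 1], t(-expr[1:25, ]))), 0)
  # eigengene summarizes the module at least as well as any single member
  set.seed(10)
  noisy <- expr + matrix(rnorm(length(expr), sd = 0.4), nrow = nrow(expr))
  me_n <- module_eigengenes(noisy, assign)
  mem <- rownames(noisy)[1:25]
  r2_me <- mean(cor(me_n[, 1], t(noisy[mem, ]))^2)
  r2_best_gene <- max(vapply(mem, function(g) {
    mean(cor(noisy[g, ], t(noisy[mem, ]))^2)
  }, numeric(1)))
  expect_gte(r2_me + 1e-9, r2_best_gene)
})

test_that("modules merge below the eigengene-dissimilarity threshold only", {
  assign <- setNames(rep(c(1L, 2L), each = 25), paste0("g", 1:50))
  near <- make_two_module_expr(0.9)   # d = 0.1 < 0.15
  merged <- merge_modules(near, assign)
  expect_equal(length(unique(merged[merged > 0])), 1)
  far <- make_two_module_expr(0.8)    # d = 0.2 >= 0.15
  kept <- merge_modules(far, assign)
  expect_equal(length(unique(kept[kept > 0])), 2)
  # label permutation leaves the partition unchanged
  assign_swapped <- setNames(rep(c(2L, 1L), each = 25), paste0("g", 1:50))
  expect_equal(adjusted_rand(merge_modules(far, assign_swapped), kept), 1)
})

test_that("kME hub calls use a strict threshold", {
  # gene engineered to correlate with the eigengene at (just under) 0.8
  me <- matrix(c(1, 2, -2, -1) / sqrt(10), ncol = 1,
               dimnames = list(paste0("s", 1:4), "ME1"))
  expr <- rbind(g1 = c(2, 1, -1, -2), g2 = c(1, 2, -2, -1))
  colnames(expr) <- paste0("s", 1:4)
  assign <- c(g1 = 1L, g2 = 1L)
  kme <- kme_and_hubs(expr, assign, me)
  expect_lte(kme$kme[1], 0.8)
  expect_false(kme$is_hub[1])            # not a hub at the boundary
  expect_true(kme$is_hub[2])             # cor = 1 member is
  # unassigned genes carry NA
  kme0 <- kme_and_hubs(expr, c(g1 = 1L, g2 = 0L), me)
  expect_true(is.na(kme0$kme[2]))
})

test_that("designated high-loading genes out-rank the rest on kME", {
  set.seed(11)
  n_s <- 24
  f <- rnorm(n_s)
  strong <- t(sapply(1:15, function(i) 0.95 * f + rnorm(n_s, sd = sqrt(1 - 0.95^2))))
  weak <- t(sapply(1:15, function(i) 0.4 * f + rnorm(n_s, sd = sqrt(1 - 0.4^2))))
  expr <- rbind(strong, weak)
  rownames(expr) <- paste0("g", 1:30); colnames(expr) <- paste0("s", 1:n_s)
  assign <- setNames(rep(1L, 30), rownames(expr))
  kme <- kme_and_hubs(expr, assign)
  expect_gt(mean(kme$kme[1:15]), mean(kme$kme[16:30]))
})

test_that("module detection is deterministic and order-equivariant", {
  cfg <- small_sim_config(seed = 12, n_genes = 150L, sizes = rep(40L, 3L),
                          module_loading = 0.9)
  sim <- simulate_expression(plant_truth(cfg), cfg, "T")
  expr <- expression_transform(sim$counts, verbose = FALSE)
  m1 <- detect_modules(expr, power = 8)
  m2 <- detect_modules(expr, power = 8)
  expect_identical(m1$assignment, m2$assignment)
  set.seed(13)
  perm <- sample(nrow(expr))
  m3 <- detect_modules(expr[perm, ], power = 8)
  common <- intersect(names(m1$assignment), names(m3$assignment))
  expect_equal(adjusted_rand(m1$assignment[common], m3$assignment[common]), 1)
})
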