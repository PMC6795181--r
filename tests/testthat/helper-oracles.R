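# Independent oracles used by the tests: exhaustive enumeration for the
# hypergeometric tail, a triple-loop topological overlap, a double-loop
# inter-set edge counter, and small deterministic fixtures.

# P(X >= k) by enumerating every n-subset of an N-gene universe whose first
# K elements are the "list" genes.
hyper_tail_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0 || K == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  succ <- colSums(subsets <= K)
  mean(succ >= k)
}

# O(n^3) topological overlap oracle.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# brute-force inter-set edge count over an edge data.frame
inter_count_oracle <- function(edges, set_a, set_b) {
  cnt <- 0
  for (r in seq_len(nrow(edges))) {
    u <- edges$protein1[r]; v <- edges$protein2[r]
    if ((u %in% set_a && v %in% set_b) || (u %in% set_b && v %in% set_a)) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# two exactly-correlated module blocks whose eigengenes have correlation rho
make_two_module_expr <- function(rho, n_samples = 8, genes_per_module = 25) {
  set.seed(99)
  v <- rnorm(n_samples); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  u <- rnorm(n_samples); u <- u - mean(u)
  u <- u - sum(u * v) * v; u <- u / sqrt(sum(u^2))
  w <- rho * v + sqrt(1 - rho^2) * u
  expr <- rbind(
    t(sapply(seq_len(genes_per_module), function(i) v * (1 + 0.01 * i))),
    t(sapply(seq_len(genes_per_module), function(i) w * (1 + 0.01 * i))))
  rownames(expr) <- paste0("g", seq_len(2 * genes_per_module))
  colnames(expr) <- paste0("s", seq_len(n_samples))
  expr
}

# tiny single-tissue simulation configuration
small_sim_config <- function(seed, n_genes = 600L, sizes = rep(60L, 5L),
                             n_case = 12L, n_control = 12L, ...) {
  sim_config(
    n_genes = n_genes, module_sizes = sizes,
    tissues = "T", tissue_modules = list(T = seq_along(sizes)),
    n_case = c(T = n_case), n_control = c(T = n_control),
    risk_modules = list(sfari = 1L, dvmt = 2L),
    tissue_specific_modules = list(T = seq_len(min(3L, length(sizes)))),
    crosstalk_pairs = list(), seed = seed, ...)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
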