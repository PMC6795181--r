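# Cross-tissue module crosstalk: tissue-specific module selection and a
# permutation test for excess PPI edges between module pairs, with random
# same-size gene-set pairs drawn from the network node set as the null.

#' Select tissue-specific modules
#'
#' Default (strict) reading: a candidate module is tissue-specific when it
#' contains at least one gene that is simultaneously a DEG and on the
#' tissue-specific gene list. The relaxed reading (`strict = FALSE`)
#' requires the module to contain a tissue-specific gene and, separately,
#' any DEG.
#'
#' @param assign named module label vector.
#' @param degs character vector of DEGs for the tissue.
#' @param tissue_genes character vector of tissue-specific genes (non-empty).
#' @param candidate_modules module labels eligible for selection.
#' @param strict logical; see Description.
#' @return Sorted integer vector of selected module labels.
#' @export
tissue_specific_modules <- function(assign, degs, tissue_genes,
                                    candidate_modules, strict = TRUE) {
  if (length(tissue_genes) == 0L) {
    stop("tissue-specific gene list is empty")
  }
  keep <- vapply(candidate_modules, function(m) {
    mem <- names(assign)[assign == m]
    if (strict) {
      any(mem %in% intersect(degs, tissue_genes))
    } else {
      any(mem %in% tissue_genes) && any(mem %in% degs)
    }
  }, logical(1))
  sort(candidate_modules[keep])
}

#' Permutation test for excess edges between two gene sets
#'
#' The observed statistic is [inter_set_edge_count()] of the two sets. Each
#' permutation draw samples two node sets of the same sizes, independently
#' and uniformly without replacement from the full network node set (overlap
#' between the draws is allowed, as module gene sets from different tissues
#' may share genes), and recounts the inter-set edges. The empirical p-value
#' is the fraction of draws with a count at least as large as observed,
#' without pseudo-count; a zero exceedance count is reported as
#' `p < 1/n_perm` via the `p_label` field.
#'
#' The two sets are put in a canonical internal order (by size, then by a
#' content hash) before sampling, so exchanging the roles of the sets leaves
#' the draws, and hence the p-value, unchanged.
#'
#' @param net igraph network defining edges and the sampling frame.
#' @param set_a,set_b character vectors of gene ids (each no larger than the
#'   node count).
#' @param n_perm number of permutation draws.
#' @param seed integer seed for the draws.
#' @param alpha significance level for the `significant` flag.
#' @return List of class `crosstalk_result` with `e_obs`, `n_perm`, `b`
#'   (exceedance count), `p`, `p_label`, `significant`.
#' @export
crosstalk_permutation_test <- function(net, set_a, set_b, n_perm = 100000L,
                                       seed, alpha = 0.05) {
  stopifnot(n_perm >= 1L)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > n || length(set_b) > n) {
    stop("set size exceeds the network node count")
  }
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both gene sets must be non-empty")
  }
  e_obs <- inter_set_edge_count(net, set_a, set_b)

  # canonical order: smaller set sampled first; ties broken by content
  key_a <- paste(sort(set_a), collapse = "|")
  key_b <- paste(sort(set_b), collapse = "|")
  if (length(set_a) > length(set_b) ||
      (length(set_a) == length(set_b) && key_a > key_b)) {
    tmp <- set_a; set_a <- set_b; set_b <- tmp
  }
  sa <- length(set_a); sb <- length(set_b)

  e <- igraph::as_edgelist(net, names = FALSE)
  e1 <- e[, 1]; e2 <- e[, 2]

  b <- with_seed(seed, {
    ma <- logical(n); mb <- logical(n)
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      ia <- sample.int(n, sa); ib <- sample.int(n, sb)
      ma[ia] <- TRUE; mb[ib] <- TRUE
      cnt <- sum((ma[e1] & mb[e2]) | (mb[e1] & ma[e2]))
      if (cnt >= e_obs) exceed <- exceed + 1L
      ma[ia] <- FALSE; mb[ib] <- FALSE
    }
    exceed
  })
  p <- b / n_perm
  structure(list(e_obs = e_obs, n_perm = as.integer(n_perm), b = b, p = p,
                 p_label = if (b == 0L) paste0("< ", format(1 / n_perm)) else
                   format(p),
                 significant = p < alpha),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat("Crosstalk permutation test: E_obs =", x$e_obs,
      "| p =", x$p_label, sprintf("(%d/%d draws)", x$b, x$n_perm),
      if (x$significant) "*" else "", "\n")
  invisible(x)
}

#' Crosstalk tests for all cross-tissue module pairs
#'
#' Runs [crosstalk_permutation_test()] for every pair of one tissue-A module
#' set with one tissue-B module set. Each pair draws its seed from an
#' independent substream keyed by the unordered pair of module names, so
#' exchanging the roles of the tissues transposes the table with identical
#' p-values, and adding a pair never perturbs another pair's draws.
#'
#' @param net igraph network (sampling frame and edge set).
#' @param modules_a,modules_b named lists of gene-id vectors (names are
#'   module labels, e.g. `"CC_M1"`).
#' @param n_perm permutation draws per pair.
#' @param seed root seed.
#' @param alpha raw-p significance level.
#' @return data.frame with `module_a`, `module_b`, `size_a`, `size_b`,
#'   `e_obs`, `n_perm`, `b`, `p`, `p_bh`, `significant`.
#' @export
all_pairs_crosstalk <- function(net, modules_a, modules_b, n_perm = 100000L,
                                seed, alpha = 0.05) {
  if (length(modules_a) == 0L || length(modules_b) == 0L) {
    stop("both module lists must be non-empty")
  }
  stopifnot(!is.null(names(modules_a)), !is.null(names(modules_b)))
  rows <- list()
  for (na in names(modules_a)) {
    for (nb in names(modules_b)) {
      key <- paste(sort(c(na, nb)), collapse = "~")
      res <- crosstalk_permutation_test(
        net, modules_a[[na]], modules_b[[nb]], n_perm = n_perm,
        seed = substream_seed(seed, "crosstalk", key), alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = na, module_b = nb,
        size_a = length(unique(modules_a[[na]])),
        size_b = length(unique(modules_b[[nb]])),
        e_obs = res$e_obs, n_perm = res$n_perm, b = res$b, p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out
}
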