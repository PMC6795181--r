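# Hypergeometric enrichment machinery: module x risk-list enrichment,
# candidate/dysfunctional module selection, generic over-representation
# against GMT collections, and pivot regulator detection.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` are in the list, the probability of observing
#' at least `k` list genes. Computed through the log-gamma based distribution
#' function, so it is numerically stable for large margins. Returns 1 when
#' `k = 0`.
#'
#' @param k observed overlap.
#' @param K list size within the universe.
#' @param n selection (e.g. module) size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (K < 0 || K > N || n < 0 || n > N) {
    stop("inconsistent margins: need 0 <= K, n <= N")
  }
  if (k < 0 || k > min(n, K)) {
    stop("overlap k must satisfy 0 <= k <= min(n, K)")
  }
  if (k == 0L) return(1)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over the non-missing p-values; `NA`s are propagated and do not
#' count toward the family size.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Module x gene-list hypergeometric enrichment
#'
#' One upper-tail test per module (label > 0): overlap of the module's genes
#' with the list, against the gene universe (by default the set of genes
#' eligible for module membership). BH adjustment across modules.
#'
#' @param assign named integer vector of module labels (0 = unassigned).
#' @param gene_list character vector; intersected with the universe first.
#' @param universe character vector of universe gene ids.
#' @return data.frame with columns `module`, `k`, `n`, `K`, `N`, `p`, `padj`,
#'   `genes` (comma-separated overlap).
#' @export
module_list_enrichment <- function(assign, gene_list, universe) {
  stopifnot(!is.null(names(assign)))
  universe <- unique(universe)
  glist <- intersect(unique(gene_list), universe)
  if (length(glist) == 0L) {
    stop("gene list has no overlap with the universe; check identifiers")
  }
  assign <- assign[names(assign) %in% universe]
  labs <- sort(unique(assign[assign > 0]))
  N <- length(universe); K <- length(glist)
  rows <- lapply(labs, function(m) {
    mem <- names(assign)[assign == m]
    ov <- intersect(mem, glist)
    data.frame(module = m, k = length(ov), n = length(mem), K = K, N = N,
               p = hypergeom_tail(length(ov), K, length(mem), N),
               genes = paste(sort(ov), collapse = ","))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(module = integer(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      genes = character())
  }
  res$padj <- bh_adjust(res$p)
  res[c("module", "k", "n", "K", "N", "p", "padj", "genes")]
}

#' Select candidate modules: contain DEGs and are smaller than a size cap
#'
#' @param assign named module label vector (0 = unassigned).
#' @param degs character vector of DEG ids.
#' @param max_size strict upper size bound (modules of exactly `max_size`
#'   genes are excluded).
#' @return Sorted integer vector of module labels.
#' @export
select_candidate_modules <- function(assign, degs, max_size = 500L) {
  labs <- sort(unique(assign[assign > 0]))
  keep <- vapply(labs, function(m) {
    mem <- names(assign)[assign == m]
    length(mem) < max_size && any(mem %in% degs)
  }, logical(1))
  labs[keep]
}

#' Flag dysfunctional modules from risk-list enrichments
#'
#' A module is dysfunctional when its raw enrichment p-value against either
#' risk list falls strictly below `alpha`.
#'
#' @param enrich_sfari,enrich_dvmt outputs of [module_list_enrichment()] on
#'   the same modules.
#' @param alpha significance level (strict).
#' @return data.frame with `module`, `p_sfari`, `p_dvmt`,
#'   `sfari_significant`, `dvmt_significant`, `dysfunctional`.
#' @export
flag_dysfunctional <- function(enrich_sfari, enrich_dvmt, alpha = 0.05) {
  mods <- sort(union(enrich_sfari$module, enrich_dvmt$module))
  p_s <- enrich_sfari$p[match(mods, enrich_sfari$module)]
  p_d <- enrich_dvmt$p[match(mods, enrich_dvmt$module)]
  sfari_sig <- !is.na(p_s) & p_s < alpha
  dvmt_sig <- !is.na(p_d) & p_d < alpha
  data.frame(module = mods, p_sfari = p_s, p_dvmt = p_d,
             sfari_significant = sfari_sig, dvmt_significant = dvmt_sig,
             dysfunctional = sfari_sig | dvmt_sig)
}

#' Over-representation analysis against a GMT collection
#'
#' Hypergeometric upper-tail test of a gene list against every set of a
#' collection, BH-adjusted across the collection and sorted by adjusted p.
#' Sets without any universe overlap are skipped with a message.
#'
#' @param gene_list character vector (deduplicated, intersected with the
#'   universe).
#' @param collection named list of character vectors (see [read_gmt()]).
#' @param universe character vector of universe gene ids.
#' @param padj_alpha significance level on the adjusted p-value.
#' @param verbose emit log messages.
#' @return data.frame with `set`, `k`, `n`, `K`, `N`, `p`, `padj`,
#'   `significant`, `genes`.
#' @export
ora_gmt <- function(gene_list, collection, universe, padj_alpha = 0.05,
                    verbose = TRUE) {
  if (length(collection) == 0L) stop("empty gene-set collection")
  universe <- unique(universe)
  glist <- intersect(unique(gene_list), universe)
  N <- length(universe); n <- length(glist)
  rows <- list()
  for (nm in names(collection)) {
    set_u <- intersect(unique(collection[[nm]]), universe)
    if (length(set_u) == 0L) {
      cx_log("ora_gmt: set '", nm, "' has no universe overlap; skipped",
             verbose = verbose)
      next
    }
    ov <- intersect(glist, set_u)
    rows[[nm]] <- data.frame(
      set = nm, k = length(ov), n = n, K = length(set_u), N = N,
      p = hypergeom_tail(length(ov), length(set_u), n, N),
      genes = paste(sort(ov), collapse = ","))
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) stop("no set of the collection overlaps the universe")
  res$padj <- bh_adjust(res$p)
  res$significant <- res$padj < padj_alpha
  res <- res[order(res$padj, res$p, res$set), ]
  rownames(res) <- NULL
  res[c("set", "k", "n", "K", "N", "p", "padj", "significant", "genes")]
}

#' Detect pivot regulators of candidate modules
#'
#' A regulator is a pivot of a module when (i) it has more than one target
#' inside the module and (ii) its target set is hypergeometrically enriched
#' in the module (raw `p < alpha`, module genes drawn against the universe).
#' A regulator may be a pivot of several modules.
#'
#' @param regmap named list of target-gene vectors with a `description`
#'   attribute carrying the regulator type (shape of [read_gmt()] output).
#' @param assign named module label vector.
#' @param candidate_modules module labels to test.
#' @param universe character vector of universe gene ids; targets are
#'   intersected with it.
#' @param alpha raw-p significance level (strict).
#' @param min_targets minimum in-module target count (criterion i; default
#'   "more than one", i.e. 2).
#' @param degs optional DEG set; when supplied, targets are additionally
#'   restricted to DEGs before testing.
#' @return data.frame with `regulator`, `type`, `module`, `k`, `K`, `n`,
#'   `N`, `p`, `padj`, `is_pivot` (one row per regulator x module).
#' @export
pivot_regulators <- function(regmap, assign, candidate_modules, universe,
                             alpha = 0.05, min_targets = 2L, degs = NULL) {
  if (length(candidate_modules) == 0L) {
    return(data.frame(regulator = character(), type = character(),
                      module = integer(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      padj = numeric(), is_pivot = logical()))
  }
  universe <- unique(universe)
  types <- attr(regmap, "description")
  assign <- assign[names(assign) %in% universe]
  N <- length(universe)
  members <- lapply(candidate_modules, function(m) names(assign)[assign == m])
  names(members) <- as.character(candidate_modules)

  rows <- list()
  for (rid in names(regmap)) {
    tg <- intersect(unique(regmap[[rid]]), universe)
    if (!is.null(degs)) tg <- intersect(tg, degs)
    K <- length(tg)
    for (m in candidate_modules) {
      mem <- members[[as.character(m)]]
      k <- length(intersect(tg, mem))
      p <- if (K == 0L || length(mem) == 0L) 1 else {
        hypergeom_tail(k, K, length(mem), N)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = rid,
        type = if (!is.null(types) && rid %in% names(types)) types[[rid]] else NA_character_,
        module = m, k = k, K = K, n = length(mem), N = N, p = p)
    }
  }
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res$is_pivot <- res$k >= min_targets & res$p < alpha
  res
}
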