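# Weighted co-expression module detection: log-normalized expression ->
# soft-thresholded |correlation| adjacency -> topological overlap ->
# average-linkage clustering -> static cut -> eigengene-based merging ->
# kME and hub calls.

#' Log-normalized expression for network construction
#'
#' `log2(count / size_factor + 1)` per gene and sample; genes with variance
#' below 1e-12 across samples are dropped (their identities are logged).
#'
#' @param counts gene-by-sample count matrix.
#' @param verbose emit log messages.
#' @return Real matrix (genes x samples).
#' @export
expression_transform <- function(counts, verbose = TRUE) {
  x <- log2(normalize_counts(counts) + 1)
  v <- apply(x, 1, var)
  drop <- v < 1e-12
  if (any(drop)) {
    cx_log("expression_transform: dropping ", sum(drop),
           " near-constant gene(s): ",
           paste(head(rownames(x)[drop], 10), collapse = ", "),
           if (sum(drop) > 10) ", ...", verbose = verbose)
    x <- x[!drop, , drop = FALSE]
  }
  x
}

#' Soft-thresholded correlation adjacency
#'
#' Unsigned network: `a_ij = |pearson(x_i, x_j)|^power` for `i != j`, with a
#' zero diagonal (self-adjacency does not contribute to connectivity).
#'
#' @param expr genes x samples matrix (>= 3 samples).
#' @param power soft-thresholding power (>= 1).
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  if (ncol(expr) < 3L) stop("adjacency requires at least 3 samples")
  if (!is.numeric(power) || power < 1) stop("power must be >= 1")
  a <- abs(cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Linear-regression R^2 of `log10 p(k)` on `log10 k` over a binned
#' connectivity histogram, the standard diagnostic for choosing the
#' soft-thresholding power.
#'
#' @param adj adjacency matrix (>= 20 genes).
#' @param n_bins number of connectivity bins.
#' @return R^2 in `[0, 1]`; 0 with a warning when connectivity is degenerate.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  if (nrow(adj) < 20L) stop("scale_free_fit requires at least 20 genes")
  k <- rowSums(adj)
  if (max(k) - min(k) < .Machine$double.eps^0.5) {
    warning("degenerate connectivity (all equal); returning 0")
    return(0)
  }
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 3L) {
    warning("fewer than 3 occupied connectivity bins; returning 0")
    return(0)
  }
  fit <- lm(log10(freq[ok]) ~ log10(kmean[ok]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu * a_uj` and connectivity `k_i = sum_u a_iu`; the
#' diagonal is set to 1 by convention.
#'
#' @param adj adjacency matrix (symmetric, entries in `[0, 1]`, zero
#'   diagonal).
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  a <- as.matrix(adj)
  stopifnot(nrow(a) == ncol(a))
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  tom
}

#' Average-linkage gene dendrogram
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @return An `hclust` object.
#' @export
cluster_dendrogram <- function(diss) {
  d <- as.matrix(diss)
  if (nrow(d) < 2L) stop("clustering requires at least 2 genes")
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-8)) {
    stop("dissimilarity must be symmetric with zero diagonal")
  }
  hclust(as.dist(d), method = "average")
}

#' Cut a dendrogram into modules
#'
#' Static cut at `cut_height`; branches with at least `min_module_size`
#' members become modules labeled `1..M` in decreasing size order (size ties
#' broken by the smallest original gene index), everything else gets the
#' unassigned label 0.
#'
#' @param dendro an `hclust` object from [cluster_dendrogram()].
#' @param min_module_size minimum module size.
#' @param cut_height static cut height on the dissimilarity scale.
#' @return Named integer vector of module labels.
#' @export
cut_modules <- function(dendro, min_module_size = 20L, cut_height = 0.99) {
  if (!(cut_height > 0 && cut_height < 1)) stop("cut_height must be in (0, 1)")
  # exact ties in merge heights can leave sub-epsilon non-monotonicity that
  # cutree refuses; flatten it (larger violations indicate a real problem)
  viol <- -min(diff(dendro$height), 0)
  if (viol > 0) {
    if (viol > 1e-8) stop("dendrogram heights decrease by ", viol)
    dendro$height <- cummax(dendro$height)
  }
  cl <- cutree(dendro, h = cut_height)
  relabel_by_size(cl, min_module_size)
}

# Relabel raw cluster ids: big clusters -> 1..M by decreasing size (ties by
# smallest original member index), small clusters -> 0.
relabel_by_size <- function(cl, min_module_size) {
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  out <- integer(length(cl))
  names(out) <- names(cl)
  if (length(big)) {
    first_idx <- vapply(big, function(b) min(which(cl == b)), integer(1))
    ord <- big[order(-sizes[big], first_idx)]
    for (i in seq_along(ord)) out[cl == ord[i]] <- i
  }
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression across samples, scaled to unit norm and
#' sign-oriented so that its mean correlation with the member genes is
#' non-negative (ties resolved toward a positive first nonzero loading).
#'
#' @param expr genes x samples matrix.
#' @param assign named module label vector (0 = unassigned).
#' @return Samples x modules matrix with columns `ME<label>`, with attribute
#'   `var_explained` (proportion of standardized variance captured).
#' @export
module_eigengenes <- function(expr, assign) {
  labs <- sort(unique(assign[assign > 0]))
  if (length(labs) == 0L) stop("no module to summarize")
  me <- matrix(NA_real_, ncol(expr), length(labs),
               dimnames = list(colnames(expr), paste0("ME", labs)))
  ve <- numeric(length(labs))
  for (i in seq_along(labs)) {
    mem <- names(assign)[assign == labs[i]]
    x <- t(expr[mem, , drop = FALSE])      # samples x genes
    xs <- scale(x)
    if (ncol(xs) == 1L) {
      v <- xs[, 1] / sqrt(sum(xs[, 1]^2))
      ve[i] <- 1
    } else {
      sv <- svd(xs, nu = 1, nv = 0)
      v <- sv$u[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    mc <- mean(cor(v, xs))
    if (mc < 0) {
      v <- -v
    } else if (mc == 0) {
      nz <- which(abs(v) > 0)[1]
      if (!is.na(nz) && v[nz] < 0) v <- -v
    }
    me[, i] <- v
  }
  attr(me, "var_explained") <- stats::setNames(ve, colnames(me))
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `d = 1 - cor(ME_a, ME_b)` while `d < merge_height`,
#' recomputing eigengenes after every merge, then relabels modules by
#' decreasing size.
#'
#' @param expr genes x samples matrix.
#' @param assign named module label vector.
#' @param merge_height eigengene dissimilarity threshold.
#' @return Named integer vector of merged module labels.
#' @export
merge_modules <- function(expr, assign, merge_height = 0.15) {
  repeat {
    labs <- sort(unique(assign[assign > 0]))
    if (length(labs) < 2L) break
    me <- module_eigengenes(expr, assign)
    d <- 1 - cor(me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= merge_height) break
    from <- labs[max(idx)]; into <- labs[min(idx)]
    assign[assign == from] <- into
  }
  # relabel by size, keeping 0 for unassigned
  labs <- sort(unique(assign[assign > 0]))
  sizes <- vapply(labs, function(m) sum(assign == m), integer(1))
  first_idx <- vapply(labs, function(m) min(which(assign == m)), integer(1))
  ord <- labs[order(-sizes, first_idx)]
  out <- integer(length(assign)); names(out) <- names(assign)
  for (i in seq_along(ord)) out[assign == ord[i]] <- i
  out
}

#' Module membership (kME) and hub genes
#'
#' `kME_i` is the Pearson correlation of gene `i`'s expression with its own
#' module's eigengene; hubs are genes with `kME` strictly greater than the
#' hub threshold. Unassigned genes get `kME = NA`.
#'
#' @param expr genes x samples matrix.
#' @param assign named module label vector.
#' @param eigengenes optional precomputed [module_eigengenes()] matrix.
#' @param hub_threshold strict kME threshold for hub calls.
#' @return data.frame with `gene_id`, `module`, `kme`, `is_hub`.
#' @export
kme_and_hubs <- function(expr, assign, eigengenes = NULL, hub_threshold = 0.8) {
  if (is.null(eigengenes)) eigengenes <- module_eigengenes(expr, assign)
  kme <- rep(NA_real_, length(assign))
  names(kme) <- names(assign)
  for (g in names(assign)) {
    m <- assign[[g]]
    if (m > 0) kme[g] <- cor(expr[g, ], eigengenes[, paste0("ME", m)])
  }
  data.frame(gene_id = names(assign), module = unname(assign),
             kme = unname(kme),
             is_hub = !is.na(kme) & kme > hub_threshold, row.names = NULL)
}

#' Full co-expression module detection
#'
#' Runs adjacency, topological overlap, average-linkage clustering, static
#' cut, eigengene merging, and kME/hub annotation in sequence.
#'
#' @param expr genes x samples matrix (output of [expression_transform()]).
#' @param power soft-thresholding power.
#' @param min_module_size minimum module size at the cut.
#' @param cut_height static cut height on `1 - TOM`.
#' @param merge_height eigengene-dissimilarity merge threshold.
#' @param hub_threshold strict kME threshold for hubs.
#' @return List of class `coexpr_modules` with `assignment`, `eigengenes`,
#'   `kme` (data.frame), `dendrogram`, and the parameters used.
#' @export
detect_modules <- function(expr, power, min_module_size = 20L,
                           cut_height = 0.99, merge_height = 0.15,
                           hub_threshold = 0.8) {
  adj <- adjacency_matrix(expr, power)
  tom <- tom_similarity(adj)
  dendro <- cluster_dendrogram(1 - tom)
  assign <- cut_modules(dendro, min_module_size, cut_height)
  if (any(assign > 0)) {
    assign <- merge_modules(expr, assign, merge_height)
    me <- module_eigengenes(expr, assign)
    kme <- kme_and_hubs(expr, assign, me, hub_threshold)
  } else {
    me <- NULL
    kme <- data.frame(gene_id = names(assign), module = 0L,
                      kme = NA_real_, is_hub = FALSE)
  }
  structure(list(assignment = assign, eigengenes = me, kme = kme,
                 dendrogram = dendro,
                 params = list(power = power,
                               min_module_size = min_module_size,
                               cut_height = cut_height,
                               merge_height = merge_height,
                               hub_threshold = hub_threshold)),
            class = "coexpr_modules")
}
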