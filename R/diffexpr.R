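# Two-group differential-expression screen: median-of-ratios normalization,
# per-gene negative-binomial Wald test with method-of-moments dispersion,
# Benjamini-Hochberg adjustment, and the |FC| > 1.2 & p < 0.05 DEG rule.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of its count to the gene's geometric mean across samples (the median
#' is taken on the log scale, so an even number of reference genes
#' interpolates geometrically). Reference genes are those with a strictly
#' positive geometric mean, i.e. positive counts in every sample.
#'
#' @param counts gene-by-sample count matrix (>= 2 samples).
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("size_factors needs at least 2 samples")
  gm <- apply(counts, 1, geomean)
  use <- gm > 0
  if (!any(use)) {
    stop("no gene has positive counts in all samples; cannot normalize")
  }
  ratios <- counts[use, , drop = FALSE] / gm[use]
  sf <- exp(apply(log(ratios), 2, median))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Normalize counts by size factors
#' @param counts gene-by-sample count matrix.
#' @param sf size factors (defaults to [size_factors()] of `counts`).
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2, sf, `/`)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene: group means of normalized counts; `log2FC = log2((mean_case +
#' c) / (mean_control + c))` with pseudo-count `c = 0.5`; a Wald statistic
#' from the NB variance model `Var = mu + alpha * mu^2` with a
#' method-of-moments dispersion estimate (the larger of the two per-group
#' estimates, floored at 1e-8) via the delta method on the log scale;
#' two-sided p-values from the standard-normal reference; BH adjustment over
#' the tested genes.
#'
#' Genes with all-zero counts in both groups are reported with `NA`
#' statistics and excluded from the BH family.
#'
#' @param counts gene-by-sample count matrix.
#' @param groups character/factor of length `ncol(counts)` with the two
#'   labels in `case`/`control`.
#' @param case,control the labels of the two groups.
#' @param fc_threshold,p_threshold thresholds for the DEG flag:
#'   `|FC| > fc_threshold` (natural scale, strict) and raw `p < p_threshold`
#'   (strict).
#' @param pseudo_count pseudo-count added to group means in the fold change.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `baseMean`, `log2FC`, `pvalue`, `padj`, `is_deg`.
#' @export
de_test <- function(counts, groups, case = "case", control = "control",
                    fc_threshold = 1.2, p_threshold = 0.05,
                    pseudo_count = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  i1 <- which(groups == case); i0 <- which(groups == control)
  if (length(i1) < 2L || length(i0) < 2L) {
    stop("de_test requires at least 2 samples per group")
  }
  q <- normalize_counts(counts)
  q1 <- q[, i1, drop = FALSE]; q0 <- q[, i0, drop = FALSE]
  m1 <- rowMeans(q1); m0 <- rowMeans(q0)
  v1 <- apply(q1, 1, var); v0 <- apply(q0, 1, var)
  n1 <- length(i1); n0 <- length(i0)
  cst <- pseudo_count

  log2fc <- log2((m1 + cst) / (m0 + cst))
  base_mean <- rowMeans(q)

  # method-of-moments NB dispersion per group; the larger of the two
  # estimates is used (robust to group-wise variance heterogeneity and
  # keeps the normal-reference Wald test calibrated at small n), floored
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a0 <- ifelse(m0 > 0, (v0 - m0) / m0^2, NA_real_)
  alpha <- pmax(ifelse(is.na(a1), -Inf, a1), ifelse(is.na(a0), -Inf, a0))
  alpha[!is.finite(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)

  var_mean1 <- (m1 + alpha * m1^2) / n1
  var_mean0 <- (m0 + alpha * m0^2) / n0
  se_log <- sqrt(var_mean1 / (m1 + cst)^2 + var_mean0 / (m0 + cst)^2)
  wald <- (log(m1 + cst) - log(m0 + cst)) / se_log
  wald[se_log == 0] <- 0
  pvalue <- 2 * pnorm(-abs(wald))

  zero_both <- rowSums(counts[, c(i1, i0), drop = FALSE]) == 0
  log2fc[zero_both] <- NA_real_
  pvalue[zero_both] <- NA_real_
  padj <- bh_adjust(pvalue)

  is_deg <- !is.na(pvalue) & abs(log2fc) > log2(fc_threshold) &
    pvalue < p_threshold
  res <- data.frame(gene_id = rownames(counts), baseMean = base_mean,
                    log2FC = log2fc, pvalue = pvalue, padj = padj,
                    is_deg = is_deg, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "thresholds") <- c(fc = fc_threshold, p = p_threshold,
                               pseudo_count = cst)
  res
}

#' Extract the DEG set from a DE result
#'
#' Genes with `|log2FC| > log2(fc_threshold)` and raw `p < p_threshold`,
#' both strict.
#'
#' @param de a `de_result` from [de_test()].
#' @param fc_threshold fold-change threshold on the natural scale (> 1).
#' @param p_threshold raw p-value threshold in (0, 1].
#' @return Character vector of gene ids.
#' @export
filter_degs <- function(de, fc_threshold = 1.2, p_threshold = 0.05) {
  if (!is.null(fc_threshold) && (!is.numeric(fc_threshold) || fc_threshold <= 1)) {
    stop("fc_threshold must be a number > 1")
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be in (0, 1]")
  }
  if (nrow(de) == 0L) return(character(0))
  keep <- !is.na(de$pvalue) & abs(de$log2FC) > log2(fc_threshold) &
    de$pvalue < p_threshold
  de$gene_id[keep]
}
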