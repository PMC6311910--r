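#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m raters each ranking the same n items:
#' `W = 12 S / (m^2 n (n^2 - 1) - m T)` with
#' `S = sum_i (R_i - m (n + 1) / 2)^2` over per-item rank sums `R_i`, and
#' `T` the usual midrank tie correction `sum over raters of (t^3 - t)`
#' summed over tie groups.
#'
#' @param ranks m x n matrix, one ranking per row. Rows are passed through
#'   [rank()] so either ranks or raw scores may be supplied; ties become
#'   midranks.
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(ranks) {
  ranks <- as.matrix(ranks)
  m <- nrow(ranks); n <- ncol(ranks)
  if (m < 2L) stop("need at least 2 raters")
  if (n < 2L) stop("need at least 2 items")
  r <- t(apply(ranks, 1L, rank))
  rsum <- colSums(r)
  s <- sum((rsum - m * (n + 1) / 2)^2)
  tie_corr <- sum(apply(r, 1L, function(v) {
    tl <- table(v)
    sum(tl^3 - tl)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_corr
  if (denom <= 0) return(0)  # every rater ties all items
  12 * s / denom
}

#' Rank-based area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half (equivalent to the
#' Wilcoxon-Mann-Whitney statistic).
#'
#' @param scores numeric score per observation (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  pos <- if (is.logical(labels)) labels
         else if (is.factor(labels)) labels == levels(labels)[2L]
         else as.numeric(labels) == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (q-values), same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank-sum competitive enrichment test
#'
#' Two-sided Wilcoxon rank-sum p-value comparing the per-gene phenotype
#' statistics of a gene set's members against all other genes. A simple
#' competitive test, useful as stand-in plumbing where externally computed
#' enrichment p-values (e.g. from CAMERA) are not supplied.
#'
#' @param gene_stats named numeric vector of per-gene statistics.
#' @param members gene-set members: character names into `gene_stats`, or a
#'   logical/integer index vector.
#' @return two-sided p-value.
#' @export
competitive_enrichment <- function(gene_stats, members) {
  if (is.character(members)) {
    members <- names(gene_stats) %in% members
  } else if (is.numeric(members)) {
    members <- seq_along(gene_stats) %in% members
  }
  inside <- gene_stats[members]
  outside <- gene_stats[!members]
  if (!length(inside)) stop("gene set has no members among the statistics")
  if (!length(outside)) stop("gene set covers every gene; no complement")
  suppressWarnings(
    stats::wilcox.test(inside, outside, alternative = "two.sided")$p.value
  )
}

#' Per-gene annotation filter scores
#'
#' The fraction of a gene's original annotations removed by the optimizer:
#' `1 - kept / original`, where kept counts original annotations still
#' nonzero in the optimized (thresholded) matrix. High scores mark genes
#' the optimizer judges inconsistent with the expression data; against
#' core/non-core labels these scores yield a full ROC curve.
#'
#' @param original binary annotation matrix (terms x genes).
#' @param optimized optimized annotation matrix, same shape.
#' @return named numeric vector per gene; `NA` for genes with no original
#'   annotation.
#' @export
gene_filter_scores <- function(original, optimized) {
  check_same_terms(original, optimized, "original", "optimized")
  n_orig <- colSums(original > 0)
  n_kept <- colSums(original > 0 & optimized > 0)
  score <- 1 - n_kept / n_orig
  score[n_orig == 0] <- NA_real_
  stats::setNames(score, colnames(original))
}
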