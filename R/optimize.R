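#' Z-score normalise a gene expression matrix
#'
#' Standardises each gene row to mean 0 and unit variance.
#'
#' @param expr genes x samples numeric matrix, at least two samples.
#' @param sd_type `"population"` (divide by sqrt(mean squared deviation),
#'   default) or `"sample"` (n - 1 denominator).
#' @return matrix of the same shape; constant rows become all-zero with a
#'   warning.
#' @export
zscore <- function(expr, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  m <- ncol(expr)
  if (m < 2L) stop("need at least 2 samples to z-score")
  mu <- rowMeans(expr)
  centred <- expr - mu
  sdv <- if (sd_type == "population") {
    sqrt(rowMeans(centred^2))
  } else {
    sqrt(rowSums(centred^2) / (m - 1L))
  }
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene row(s) set to zero")
    sdv[flat] <- 1
  }
  out <- centred / sdv
  out[flat, ] <- 0
  out
}

#' Select differentially expressed genes by Welch t-test
#'
#' @param expr genes x samples matrix.
#' @param groups per-sample labels with exactly two levels, each with at
#'   least two samples.
#' @param alpha significance level; genes with `p < alpha` are kept.
#' @return character vector of selected genes, preserving row order. Genes
#'   with an undefined statistic (zero variance in both groups) are never
#'   selected.
#' @export
de_filter <- function(expr, groups, alpha = 0.05) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  groups <- as.factor(as.character(groups))
  if (length(groups) != ncol(expr)) stop("one group label per sample required")
  lev <- levels(groups)
  if (length(lev) != 2L) stop("exactly two groups required, got ", length(lev))
  n1 <- sum(groups == lev[1L]); n2 <- sum(groups == lev[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  x1 <- expr[, groups == lev[1L], drop = FALSE]
  x2 <- expr[, groups == lev[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  # alpha = 1 means "no filtering": keep every gene with a computable p,
  # including degenerate p = 1 cases
  keep <- !is.na(p) & (if (alpha >= 1) TRUE else p < alpha)
  rn <- rownames(expr)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(expr)))
  rn[keep]
}

#' Cluster genes into a one-hot category matrix
#'
#' Runs k-means on the gene expression profiles (rows) and encodes the
#' partition as the category matrix C: one row per gene, one column per
#' cluster, a single 1 per row.
#'
#' @param expr genes x samples matrix (normally z-scored).
#' @param k number of clusters, `1 <= k <= nrow(expr)`.
#' @param seed integer seed; the same seed always yields the same partition.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return n x k 0/1 matrix with gene row names.
#' @export
cluster_partition <- function(expr, k, seed, nstart = 5L) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  n <- nrow(expr)
  if (k < 1L || k > n) stop("k must be between 1 and the number of genes")
  cl <- if (k == 1L) {
    rep(1L, n)
  } else {
    with_seed(seed,
      stats::kmeans(expr, centers = k, nstart = nstart, iter.max = 100L)$cluster)
  }
  cmat <- matrix(0, n, k, dimnames = list(rownames(expr), NULL))
  cmat[cbind(seq_len(n), cl)] <- 1
  cmat
}

#' Annotation statistic matrix
#'
#' `S = A %*% C`, then each nonzero row is divided by its sum so row `i`
#' gives the share of term `i`'s (probabilistic) annotation mass falling in
#' each expression cluster.
#'
#' @param a annotation matrix, terms x genes.
#' @param cmat one-hot category matrix, genes x clusters.
#' @return t x k matrix whose nonzero rows sum to 1; all-zero rows (terms
#'   annotating nothing) stay zero and are reported via a message.
#' @export
annotation_statistic <- function(a, cmat) {
  if (ncol(a) != nrow(cmat)) stop("gene dimension mismatch between A and C")
  if (!is.null(colnames(a)) && !is.null(rownames(cmat)) &&
      !identical(colnames(a), rownames(cmat))) {
    stop("gene order mismatch between A and C")
  }
  s <- a %*% cmat
  rs <- rowSums(s)
  zero <- rs == 0
  if (any(zero)) message(sum(zero), " all-zero term row(s) left unnormalised")
  s[!zero, ] <- s[!zero, , drop = FALSE] / rs[!zero]
  s
}

#' One annotation-filtering step at a fixed clustering
#'
#' For each term the dominant cluster `kmax` is the column of its
#' statistic row with maximal share (ties, compared at tolerance
#' `tie_tol`, are broken uniformly at random). Each annotation is kept
#' only for genes in the dominant cluster and scaled by that share:
#' `a*_ij = a_ij * c_j,kmax * s_i,kmax`.
#'
#' @param a annotation matrix, terms x genes.
#' @param cmat genes x clusters one-hot matrix.
#' @param s row-normalised statistic matrix from [annotation_statistic()].
#' @param tie_tol values within `tie_tol` of the row maximum count as tied.
#' @return terms x genes matrix; uses the current RNG stream for
#'   tie-breaks, so seed it (e.g. via the callers below) for reproducibility.
#' @export
optimize_step <- function(a, cmat, s, tie_tol = 1e-12) {
  t_n <- nrow(a)
  kmax <- integer(t_n)
  for (i in seq_len(t_n)) {
    row <- s[i, ]
    cand <- which(row >= max(row) - tie_tol)
    kmax[[i]] <- if (length(cand) > 1L) cand[[sample.int(length(cand), 1L)]]
                 else cand[[1L]]
  }
  # row i of the result: a[i, ] masked by membership of cluster kmax_i and
  # scaled by that cluster's share s[i, kmax_i]
  mask <- t(cmat[, kmax, drop = FALSE])
  a * mask * s[cbind(seq_len(t_n), kmax)]
}

#' Consensus filtering over a range of cluster counts
#'
#' Clusters the expression data once per `k` in `k_min..k_max`, applies
#' [optimize_step()] at each, and averages the optimized matrices.
#'
#' @param a annotation matrix, terms x genes; columns must line up with the
#'   rows of `expr`.
#' @param expr genes x samples matrix (normally z-scored).
#' @param k_min,k_max inclusive cluster-count range (`k_min >= 2`).
#' @param seed master seed; per-k clustering and tie-break streams derive
#'   from it.
#' @return terms x genes averaged optimized annotation matrix.
#' @export
optimize_over_k <- function(a, expr, k_min = 3L, k_max = 15L, seed = 1L) {
  if (k_min < 2L) stop("k_min must be at least 2")
  if (k_max < k_min) stop("empty cluster-count range")
  if (k_max > nrow(expr)) stop("k_max exceeds the number of genes")
  if (ncol(a) != nrow(expr)) stop("A columns must match expression rows")

  acc <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(a))
  for (k in seq.int(k_min, k_max)) {
    cmat <- cluster_partition(expr, k, seed = child_seed(seed, k))
    s <- annotation_statistic(a, cmat)
    step <- with_seed(child_seed(seed, 100000L + k),
                      optimize_step(a, cmat, s))
    acc <- acc + step
  }
  acc / (k_max - k_min + 1L)
}

#' Consensus filtering over bootstrap resamples
#'
#' Draws `n_boot` bootstrap resamples of the samples (columns, with
#' replacement), re-z-scores each replicate, runs [optimize_over_k()] on
#' it, and averages the resulting matrices.
#'
#' @inheritParams optimize_over_k
#' @param n_boot number of bootstrap resamples.
#' @return terms x genes final averaged optimized annotation matrix, fully
#'   determined by `seed`.
#' @export
bootstrap_optimize <- function(a, expr, k_min = 3L, k_max = 15L,
                               n_boot = 50L, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  m <- ncol(expr)
  acc <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(a))
  for (b in seq_len(n_boot)) {
    idx <- with_seed(child_seed(seed, 200000L + b),
                     sample.int(m, m, replace = TRUE))
    eb <- suppressWarnings(zscore(expr[, idx, drop = FALSE]))
    acc <- acc + optimize_over_k(a, eb, k_min, k_max,
                                 seed = child_seed(seed, 300000L + b))
  }
  acc / n_boot
}

#' Threshold an optimized annotation matrix
#'
#' @param a_final optimized annotation matrix.
#' @param tau entries strictly below `tau` are set to 0 (default 0.1).
#' @param binarize also set surviving entries to 1.
#' @return thresholded matrix.
#' @export
apply_threshold <- function(a_final, tau = 0.1, binarize = FALSE) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  a_final[a_final < tau] <- 0
  if (binarize) a_final[a_final > 0] <- 1
  a_final
}
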