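#' Information content of ontology terms
#'
#' Corpus-based (Resnik-style) information content: for each term,
#' `IC = -log(n_term / n_root)` where `n_term` counts genes annotated by the
#' term in a true-path-closed annotation matrix and `n_root` counts genes
#' annotated at the root (i.e. with any annotation at all). Natural log.
#'
#' @param annotations binary annotation matrix (terms x genes), closed under
#'   the true-path rule, rows in `dag` term order.
#' @param dag an [ontology_dag].
#' @return named numeric vector of IC values in `dag` term order, with
#'   attribute `corpus_size` (number of genes annotated at the root). Terms
#'   annotating no gene get `Inf` and are excluded from similarity.
#' @details Closure makes annotation counts descendant-inclusive, so IC is
#'   non-decreasing from ancestor to descendant and `IC(root) = 0`.
#' @export
information_content <- function(annotations, dag) {
  if (!identical(rownames(annotations), dag$terms)) {
    stop("annotation rows must match dag term order")
  }
  counts <- rowSums(annotations > 0)
  n_root <- counts[[dag$root]]
  if (n_root == 0) stop("no gene is annotated at the root; empty corpus")
  ic <- -log(counts / n_root)  # zero counts give Inf
  structure(stats::setNames(ic, dag$terms), corpus_size = n_root)
}

#' Lin semantic similarity between two terms
#'
#' `lin(a, b) = 2 IC(MICA) / (IC(a) + IC(b))`, where the MICA is the common
#' ancestor of `a` and `b` (inclusive of `a` and `b` themselves) with the
#' largest finite information content. Returns 0 when `IC(a) + IC(b) = 0`
#' (e.g. one argument is the root), so the similarity is always defined.
#'
#' @param ic information-content vector from [information_content()].
#' @param dag an [ontology_dag].
#' @param a,b term identifiers with finite IC.
#' @return similarity in `[0, 1]`.
#' @export
lin_similarity <- function(ic, dag, a, b) {
  for (tm in c(a, b)) {
    if (!tm %in% dag$terms) stop("unknown term: ", tm)
    if (!is.finite(ic[[tm]])) stop("term has infinite IC (zero frequency): ", tm)
  }
  denom <- ic[[a]] + ic[[b]]
  if (denom == 0) return(0)
  common <- intersect(c(a, ancestors(dag, a)), c(b, ancestors(dag, b)))
  vals <- ic[common]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(0)
  2 * max(vals) / denom
}

#' Pairwise Lin similarity matrix
#'
#' @param ic information-content vector from [information_content()].
#' @param dag an [ontology_dag].
#' @return symmetric t x t matrix of Lin similarities in `dag` term order.
#'   Terms with infinite IC (never annotated in the corpus) get an all-zero
#'   row and column; the diagonal is 1 for every term with positive finite
#'   IC and 0 for zero-IC terms such as the root.
#' @export
similarity_matrix <- function(ic, dag) {
  t_n <- length(dag$terms)
  ssm <- matrix(0, t_n, t_n, dimnames = list(dag$terms, dag$terms))
  anc <- ancestor_matrix(dag, inclusive = TRUE)
  finite <- is.finite(ic)
  icf <- ifelse(finite, ic, -Inf)  # infinite-IC terms can never be a MICA
  idx <- which(finite)
  for (ii in seq_along(idx)) {
    i <- idx[[ii]]
    for (j in idx[seq_len(ii)]) {
      denom <- ic[[i]] + ic[[j]]
      if (denom == 0) next
      mica <- max(icf[anc[, i] & anc[, j]])
      if (is.finite(mica) && mica > 0) {
        s <- 2 * mica / denom
        ssm[i, j] <- s
        ssm[j, i] <- s
      }
    }
  }
  ssm
}
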