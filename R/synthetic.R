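#' Generate a synthetic rooted ontology DAG
#'
#' A balanced tree of given depth and branching factor, optionally enriched
#' with extra cross edges (an additional parent drawn from a strictly
#' shallower level, which keeps the graph acyclic and single-rooted).
#'
#' @param levels tree depth including the root (`levels = 1` is a single
#'   root).
#' @param branching children per internal term.
#' @param cross_p probability that a term at level 3 or deeper gains one
#'   extra non-tree parent.
#' @param seed integer seed; the DAG is fully determined by it.
#' @return an [ontology_dag] with `sum(branching^(0:(levels-1)))` terms.
#' @export
generate_dag <- function(levels, branching, cross_p = 0, seed = 1L) {
  if (levels < 1L || branching < 1L) stop("levels and branching must be >= 1")
  n_per_level <- branching^(0:(levels - 1L))
  total <- sum(n_per_level)
  ids <- sprintf("SYN:%07d", seq_len(total))
  level_of <- rep(seq_len(levels), n_per_level)

  edges <- NULL
  offset <- cumsum(c(0L, n_per_level))
  for (lv in seq_len(levels - 1L)) {
    parents_idx <- offset[lv] + seq_len(n_per_level[lv])
    children_idx <- offset[lv + 1L] + seq_len(n_per_level[lv + 1L])
    edges <- rbind(edges,
                   cbind(parent = ids[rep(parents_idx, each = branching)],
                         child = ids[children_idx]))
  }

  if (cross_p > 0 && levels >= 3L) {
    edges <- with_seed(seed, {
      for (i in which(level_of >= 3L)) {
        if (stats::runif(1L) < cross_p) {
          shallower <- which(level_of < level_of[i] &
                               level_of > 1L)  # skip root: already an ancestor
          cand <- setdiff(ids[shallower], edges[edges[, 2L] == ids[i], 1L])
          if (length(cand)) {
            extra <- cand[sample.int(length(cand), 1L)]
            edges <- rbind(edges, cbind(parent = extra, child = ids[i]))
          }
        }
      }
      edges
    })
  }
  ontology_dag(ids, edges)
}

#' Plant a synthetic annotation ground truth on a DAG
#'
#' Genes are split into `k_true` balanced clusters. Each leaf term is
#' assigned a home cluster (cyclically over leaves); each gene of the home
#' cluster is annotated to the leaf with probability `annot_prob`. A
#' fraction `p_inconsistent` of these leaf annotations is then made
#' inconsistent: the annotation is moved to a random gene from a different
#' cluster and flagged. Finally all annotations are closed under the
#' true-path rule.
#'
#' @param dag an [ontology_dag].
#' @param n_genes number of genes.
#' @param k_true number of planted clusters (>= 2).
#' @param p_inconsistent probability in `[0, 1)` that a leaf annotation is
#'   planted inconsistently.
#' @param seed integer seed.
#' @param annot_prob probability that a home-cluster gene is annotated to a
#'   given leaf.
#' @return list of class `synthetic_truth`: `dag`, `annotations` (closed
#'   binary matrix, terms x genes), `cluster_labels` (named integer vector),
#'   `leaf_pairs` (data frame `term`, `gene`, `inconsistent`),
#'   `inconsistent_mask` (terms x genes logical, support at leaf level), and
#'   `params`.
#' @export
generate_truth <- function(dag, n_genes, k_true, p_inconsistent, seed = 1L,
                           annot_prob = 0.5) {
  if (k_true < 2L) stop("k_true must be at least 2")
  if (p_inconsistent < 0 || p_inconsistent >= 1) {
    stop("p_inconsistent must be in [0, 1)")
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  leaves <- dag_leaves(dag)

  res <- with_seed(seed, {
    labels <- sample(rep_len(seq_len(k_true), n_genes))
    home <- rep_len(seq_len(k_true), length(leaves))
    pairs <- NULL
    for (li in seq_along(leaves)) {
      in_home <- which(labels == home[li])
      hit <- in_home[stats::runif(length(in_home)) < annot_prob]
      if (!length(hit)) next
      bad <- stats::runif(length(hit)) < p_inconsistent
      gene_idx <- hit
      for (w in which(bad)) {
        pool <- setdiff(which(labels != home[li]), gene_idx)
        gene_idx[w] <- pool[sample.int(length(pool), 1L)]
      }
      pairs <- rbind(pairs, data.frame(term = leaves[li],
                                       gene = genes[gene_idx],
                                       inconsistent = bad))
    }
    list(labels = labels, pairs = pairs)
  })
  if (is.null(res$pairs)) stop("no annotations generated; raise annot_prob")

  ann <- true_path_closure(res$pairs[, c("gene", "term")], dag)
  # keep all genes as columns, even never-annotated ones, in gene order
  full <- matrix(0, length(dag$terms), n_genes,
                 dimnames = list(dag$terms, genes))
  full[, colnames(ann)] <- ann
  mask <- matrix(FALSE, length(dag$terms), n_genes,
                 dimnames = list(dag$terms, genes))
  flagged <- res$pairs[res$pairs$inconsistent, , drop = FALSE]
  mask[cbind(match(flagged$term, dag$terms), match(flagged$gene, genes))] <- TRUE

  structure(
    list(dag = dag, annotations = full,
         cluster_labels = stats::setNames(res$labels, genes),
         leaf_pairs = res$pairs, inconsistent_mask = mask,
         params = list(n_genes = n_genes, k_true = k_true,
                       p_inconsistent = p_inconsistent,
                       annot_prob = annot_prob, seed = seed)),
    class = "synthetic_truth"
  )
}

#' Generate an expression matrix with planted gene clusters
#'
#' Each cluster has a mean profile whose per-sample entries are drawn so
#' that two cluster centres differ by `effect * noise_sd` per dimension in
#' root-mean-square; genes are their cluster's profile plus iid Gaussian
#' noise. `effect = 0` yields clusters with no expression signal.
#'
#' @param cluster_labels named integer vector of per-gene cluster labels
#'   (names become row names).
#' @param n_samples number of samples (>= 4).
#' @param effect centre separation in units of `noise_sd`.
#' @param noise_sd standard deviation of the per-entry Gaussian noise.
#' @param seed integer seed.
#' @return genes x samples matrix with sample names `s1, s2, ...`.
#' @export
generate_expression <- function(cluster_labels, n_samples, effect = 2,
                                noise_sd = 1, seed = 1L) {
  if (n_samples < 4L) stop("need at least 4 samples")
  k <- max(cluster_labels)
  n <- length(cluster_labels)
  with_seed(seed, {
    centres <- matrix(stats::rnorm(k * n_samples,
                                   sd = effect * noise_sd / sqrt(2)),
                      k, n_samples)
    noise <- matrix(stats::rnorm(n * n_samples, sd = noise_sd), n, n_samples)
    out <- centres[cluster_labels, , drop = FALSE] + noise
    dimnames(out) <- list(names(cluster_labels),
                          paste0("s", seq_len(n_samples)))
    out
  })
}
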