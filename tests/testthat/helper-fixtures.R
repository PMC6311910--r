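# Shared fixtures and independent oracles.

# package-internal seeding helpers, reused to reconstruct reference streams
child_seed_for_test <- goannopt:::child_seed
with_seed_for_test <- goannopt:::with_seed

chain_dag <- function() {
  ontology_dag(c("r", "a", "b"), rbind(c("r", "a"), c("a", "b")))
}

diamond_dag <- function() {
  ontology_dag(c("r", "a", "b", "c"),
               rbind(c("r", "a"), c("r", "b"), c("a", "c"), c("b", "c")))
}

# corpus r:{g1,g2,g3}, a:{g1,g2}, b:{g1} on the chain
chain_corpus <- function() {
  dag <- chain_dag()
  ann <- true_path_closure(
    data.frame(gene = c("g1", "g2", "g3"), term = c("b", "a", "r")), dag)
  list(dag = dag, ann = ann, ic = information_content(ann, dag))
}

# Random DAG with a random edge-weighted transition matrix; the DAG is a
# random tree plus cross edges, similarities are iid uniform.
random_transition <- function(t_n, seed, cross_p = 0.3) {
  set.seed(seed)
  parents <- c(NA, vapply(2:t_n, function(i) sample.int(i - 1L, 1L), 1L))
  ids <- sprintf("t%03d", seq_len(t_n))
  edges <- cbind(ids[parents[-1L]], ids[2:t_n])
  for (i in 3:t_n) {
    if (stats::runif(1) < cross_p) {
      extra <- sample.int(i - 1L, 1L)
      if (extra != parents[i]) edges <- rbind(edges, c(ids[extra], ids[i]))
    }
  }
  dag <- ontology_dag(ids, edges)
  ssm <- matrix(stats::runif(t_n^2), t_n, t_n, dimnames = list(ids, ids))
  ssm <- (ssm + t(ssm)) / 2
  list(dag = dag, transition = transition_matrix(ssm, adjacency_matrix(dag)))
}

# Brute-force reachability ancestors: repeated boolean matrix products.
oracle_ancestors <- function(dag, term) {
  adj <- adjacency_matrix(dag) > 0
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  rownames(reach)[reach[, term]]
}

# Exhaustive common-ancestor Lin similarity.
oracle_lin <- function(ic, dag, a, b) {
  denom <- ic[[a]] + ic[[b]]
  if (denom == 0) return(0)
  common <- intersect(c(a, oracle_ancestors(dag, a)),
                      c(b, oracle_ancestors(dag, b)))
  vals <- ic[common][is.finite(ic[common])]
  if (!length(vals) || max(vals) <= 0) return(0)
  2 * max(vals) / denom
}

# Closed-form steady state.
oracle_steady_state <- function(transition, beta) {
  (1 - beta) * solve(diag(nrow(transition)) - beta * transition)
}

# Direct evaluation of the concordance formula (no ties assumed).
oracle_kendalls_w <- function(ranks) {
  m <- nrow(ranks); n <- ncol(ranks)
  rsum <- colSums(ranks)
  s <- sum((rsum - m * (n + 1) / 2)^2)
  12 * s / (m^2 * n * (n^2 - 1))
}

# Pairwise-enumeration AUC.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# Min-over-tail closed form for Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o][rank_i:n] * n / (rank_i:n)))
  }
  q
}
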