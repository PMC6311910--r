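test_that("zscore standardises rows under both sd conventions", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL))
  expect_equal(unname(zscore(m)[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(zscore(m, sd_type = "sample")[1, ]), c(-1, 0, 1))

  expect_warning(z <- zscore(rbind(g1 = c(5, 5, 5), g2 = c(1, 2, 3))),
                 "constant")
  expect_equal(unname(z["g1", ]), c(0, 0, 0))

  set.seed(1)
  big <- matrix(rnorm(200), 20, 10)
  expect_true(all(abs(rowMeans(zscore(big))) < 1e-12))
  expect_true(all(abs(rowMeans(zscore(big)^2) - 1) < 1e-12))
  expect_error(zscore(matrix(1, 2, 1)), "at least 2 samples")
})

test_that("de_filter implements the Welch two-sample t-test", {
  set.seed(42)
  expr <- rbind(flat = rep(1:2, 10),
                shifted = c(rnorm(10), rnorm(10, mean = 3)))
  groups <- rep(c("A", "B"), each = 10)
  # agreement with stats::t.test per gene
  for (g in rownames(expr)) {
    p_ref <- stats::t.test(expr[g, groups == "A"],
                           expr[g, groups == "B"])$p.value
    in_set <- g %in% de_filter(expr, groups, alpha = p_ref + 1e-9)
    out_set <- g %in% de_filter(expr, groups, alpha = p_ref * (1 - 1e-9))
    expect_true(in_set)
    expect_false(out_set)
  }
  expect_identical(de_filter(expr, groups, alpha = 0.05), "shifted")
  expect_setequal(de_filter(expr, groups, alpha = 1), rownames(expr))
  expect_error(de_filter(expr, rep("A", 20)), "two groups")
  expect_error(de_filter(expr, c(rep("A", 19), "B")), "at least 2 samples")
})

test_that("a 3-sd shift with n = 20 per group is detected essentially always", {
  hits <- 0L
  for (rep_i in 1:200) {
    set.seed(rep_i)
    expr <- matrix(c(rnorm(20), rnorm(20, mean = 3)), 1, 40,
                   dimnames = list("g", NULL))
    hits <- hits + (length(de_filter(expr, rep(c("A", "B"), each = 20))) == 1L)
  }
  expect_gte(hits / 200, 0.99)
})

test_that("cluster_partition is one-hot, seeded, and recovers planted blobs", {
  set.seed(7)
  labels <- rep(1:2, each = 25)
  expr <- matrix(rnorm(50 * 8), 50, 8) + 5 * (labels - 1.5)
  rownames(expr) <- paste0("g", 1:50)

  c1 <- cluster_partition(expr, k = 1, seed = 1)
  expect_equal(unname(c1), matrix(1, 50, 1))

  c2 <- cluster_partition(expr, k = 2, seed = 1)
  expect_true(all(rowSums(c2) == 1))
  found <- apply(c2, 1L, which.max)
  expect_true(all(found[labels == 1] == found[1]) &&
                all(found[labels == 2] == found[50]) &&
                found[1] != found[50])

  expect_identical(cluster_partition(expr, k = 4, seed = 9),
                   cluster_partition(expr, k = 4, seed = 9))
  expect_error(cluster_partition(expr, k = 51, seed = 1), "between 1")
})

test_that("annotation_statistic row-normalises A %*% C", {
  a <- rbind(t1 = c(1, 1, 1, 0.3), t2 = c(0, 0, 0, 0))
  colnames(a) <- paste0("g", 1:4)
  cmat <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                 dimnames = list(paste0("g", 1:4), NULL))
  expect_message(s <- annotation_statistic(a, cmat), "all-zero")
  expect_equal(unname(s["t1", ]), c(2 / 3.3, 1.3 / 3.3))
  expect_equal(unname(s["t2", ]), c(0, 0))
  expect_error(annotation_statistic(a, cmat[1:3, ]), "mismatch")

  # nonzero rows always sum to one
  set.seed(3)
  a2 <- matrix(runif(60), 6, 10)
  c2 <- diag(1, 10)[, 1:4] * 0
  cl <- sample(1:4, 10, replace = TRUE)
  c2 <- matrix(0, 10, 4); c2[cbind(1:10, cl)] <- 1
  s2 <- annotation_statistic(a2, c2)
  expect_true(all(abs(rowSums(s2) - 1) < 1e-12))
})

test_that("optimize_step keeps only the dominant cluster, scaled by its share", {
  a <- rbind(t1 = c(1, 1, 1, 0.3))
  colnames(a) <- paste0("g", 1:4)
  cmat <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                 dimnames = list(paste0("g", 1:4), NULL))
  s <- annotation_statistic(a, cmat)
  out <- optimize_step(a, cmat, s)
  expect_equal(unname(out[1, ]), c(2 / 3.3, 2 / 3.3, 0, 0))

  # fully consistent term: share 1, values preserved in its cluster
  a_cons <- rbind(t1 = c(0.8, 0.5, 0, 0))
  colnames(a_cons) <- paste0("g", 1:4)
  s_cons <- annotation_statistic(a_cons, cmat)
  expect_equal(unname(optimize_step(a_cons, cmat, s_cons)[1, ]),
               c(0.8, 0.5, 0, 0))

  # exact ties are broken uniformly at random
  a_tie <- rbind(t1 = c(1, 1, 1, 1))
  colnames(a_tie) <- paste0("g", 1:4)
  s_tie <- annotation_statistic(a_tie, cmat)
  picks <- vapply(1:1000, function(i) {
    set.seed(i)
    unname(optimize_step(a_tie, cmat, s_tie)[1, 1]) > 0
  }, logical(1L))
  expect_gt(mean(picks), 0.45)
  expect_lt(mean(picks), 0.55)
})

test_that("optimize_over_k averages per-k runs and favours consistent genes", {
  set.seed(11)
  labels <- rep(1:3, each = 20)
  genes <- paste0("g", 1:60)
  expr <- matrix(rnorm(60 * 12), 60, 12,
                 dimnames = list(genes, NULL)) + 4 * labels
  a <- matrix(0, 3, 60, dimnames = list(c("t1", "t2", "t3"), genes))
  for (tm in 1:3) a[tm, labels == tm] <- 1
  # plant inconsistent annotations: term 1 also annotates 4 cluster-3 genes
  incons <- genes[labels == 3][1:4]
  a["t1", incons] <- 1

  one_k <- optimize_over_k(a, expr, k_min = 3, k_max = 3, seed = 5)
  cmat <- cluster_partition(expr, 3, seed = child_seed_for_test(5, 3))
  s <- annotation_statistic(a, cmat)
  ref <- with_seed_for_test(child_seed_for_test(5, 100003L),
                            optimize_step(a, cmat, s))
  expect_equal(one_k, ref)

  avg <- optimize_over_k(a, expr, k_min = 2, k_max = 5, seed = 5)
  cons <- a["t1", ] == 1 & labels == 1
  expect_gt(min(avg["t1", cons]), max(avg["t1", incons]))
  expect_error(optimize_over_k(a, expr, k_min = 5, k_max = 4, seed = 1),
               "empty")
  expect_error(optimize_over_k(a, expr, k_min = 2, k_max = 100, seed = 1),
               "exceeds")
})

test_that("bootstrap_optimize is deterministic, bounded, seed-stable", {
  genes <- paste0("g", 1:45)
  labels <- stats::setNames(rep(1:3, each = 15), genes)
  # per-sample cluster profiles, so the signal survives the per-row
  # re-z-scoring inside the bootstrap
  expr <- generate_expression(labels, 16, effect = 4, noise_sd = 1, seed = 21)
  a <- matrix(0, 3, 45, dimnames = list(c("t1", "t2", "t3"), genes))
  for (tm in 1:3) a[tm, labels == tm] <- 1

  b1 <- bootstrap_optimize(a, expr, k_min = 2, k_max = 4, n_boot = 3, seed = 2)
  b2 <- bootstrap_optimize(a, expr, k_min = 2, k_max = 4, n_boot = 3, seed = 2)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 1))

  single <- bootstrap_optimize(a, expr, k_min = 2, k_max = 4, n_boot = 1,
                               seed = 7)
  idx <- with_seed_for_test(child_seed_for_test(7, 200001L),
                            sample.int(16, 16, replace = TRUE))
  ref <- optimize_over_k(a, zscore(expr[, idx]), k_min = 2, k_max = 4,
                         seed = child_seed_for_test(7, 300001L))
  expect_equal(single, ref)

})

test_that("bootstrap consensus is stable across master seeds", {
  # planted-cluster study at realistic scale; two independent master seeds
  # must agree on the consensus matrix almost perfectly
  dag <- generate_dag(3, 3, seed = 1)
  truth <- generate_truth(dag, 200, 3, p_inconsistent = 0.2, seed = 2,
                          annot_prob = 0.5)
  expr <- zscore(generate_expression(truth$cluster_labels, 40, effect = 2,
                                     noise_sd = 1, seed = 3))
  s1 <- bootstrap_optimize(truth$annotations, expr, k_min = 3, k_max = 8,
                           n_boot = 50, seed = 101)
  s2 <- bootstrap_optimize(truth$annotations, expr, k_min = 3, k_max = 8,
                           n_boot = 50, seed = 202)
  nz <- s1 > 0 | s2 > 0
  expect_gt(stats::cor(s1[nz], s2[nz]), 0.95)
})

test_that("apply_threshold zeroes strictly-below-tau entries", {
  m <- matrix(c(0.05, 0.1, 0.6), 1, 3)
  expect_equal(unname(apply_threshold(m, 0.1)[1, ]), c(0, 0.1, 0.6))
  expect_equal(apply_threshold(m, 0), m)
  expect_equal(unname(apply_threshold(m, 0.1, binarize = TRUE)[1, ]),
               c(0, 1, 1))
  # nonzero count non-increasing in tau
  set.seed(2)
  v <- matrix(runif(100), 10, 10)
  nz <- vapply(seq(0, 1, 0.1), function(tau) sum(apply_threshold(v, tau) > 0),
               numeric(1L))
  expect_true(all(diff(nz) <= 0))
  expect_error(apply_threshold(m, 1.5), "tau")
})
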