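test_that("ontology_dag validates structure and detects cycles", {
  dag <- chain_dag()
  expect_s3_class(dag, "ontology_dag")
  expect_identical(dag$root, "r")
  expect_identical(dag$terms, c("r", "a", "b"))

  expect_error(ontology_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
               "cycle")
  expect_error(ontology_dag(c("r", "a", "b"), rbind(c("r", "a"))),
               "exactly one root")
  expect_error(ontology_dag(c("a"), rbind(c("a", "a"))), "cycle")
})

test_that("parse_obo reads terms, drops obsolete, filters namespace", {
  doc <- c("format-version: 1.2", "",
           "[Term]", "id: GO:1", "name: root",
           "namespace: biological_process", "",
           "[Term]", "id: GO:2", "name: a",
           "namespace: biological_process",
           "is_a: GO:1 ! root", "",
           "[Term]", "id: GO:3", "name: b",
           "namespace: biological_process",
           "is_a: GO:2", "")
  dag <- parse_obo(doc)
  expect_length(dag$terms, 3L)
  expect_identical(dag$root, "GO:1")
  expect_identical(sum(lengths(dag$parents)), 2L)

  dag2 <- parse_obo(c(doc, "is_obsolete: true"))  # marks the last term
  expect_length(dag2$terms, 2L)
  expect_identical(sum(lengths(dag2$parents)), 1L)

  expect_error(parse_obo(doc[1:7], namespace = "cellular_component"),
               "no terms in namespace")

  cyc <- c("[Term]", "id: A", "namespace: biological_process", "is_a: B", "",
           "[Term]", "id: B", "namespace: biological_process", "is_a: A", "")
  expect_error(parse_obo(cyc), "cycle")
})

test_that("parse_obo synthesises a virtual root over multiple namespace roots", {
  doc <- c("[Term]", "id: R1", "namespace: biological_process", "",
           "[Term]", "id: R2", "namespace: biological_process", "",
           "[Term]", "id: C", "namespace: biological_process",
           "is_a: R1", "is_a: R2", "")
  expect_message(dag <- parse_obo(doc), "virtual root")
  expect_length(dag$terms, 4L)
  expect_identical(dag$root, "VIRTUAL:ROOT")
  expect_setequal(ancestors(dag, "C"), c("R1", "R2", "VIRTUAL:ROOT"))
})

test_that("part_of edges are included only on request", {
  doc <- c("[Term]", "id: R", "namespace: biological_process", "",
           "[Term]", "id: P", "namespace: biological_process", "is_a: R", "",
           "[Term]", "id: Q", "namespace: biological_process", "is_a: R",
           "relationship: part_of P", "")
  expect_length(ancestors(parse_obo(doc), "Q"), 1L)
  expect_setequal(ancestors(parse_obo(doc, include_part_of = TRUE), "Q"),
                  c("P", "R"))
})

test_that("ancestors matches brute-force reachability", {
  dag <- chain_dag()
  expect_length(ancestors(dag, "r"), 0L)
  expect_setequal(ancestors(dag, "b"), c("a", "r"))
  expect_error(ancestors(dag, "zzz"), "unknown term")

  dd <- diamond_dag()
  expect_setequal(ancestors(dd, "c"), c("a", "b", "r"))

  for (seed in 1:5) {
    rt <- random_transition(15L, seed)
    for (tm in sample(rt$dag$terms, 5L)) {
      expect_setequal(ancestors(rt$dag, tm), oracle_ancestors(rt$dag, tm))
    }
  }
})

test_that("adjacency_matrix marks exactly the parent edges", {
  adj <- adjacency_matrix(chain_dag())
  expect_equal(sum(adj), 2)
  expect_equal(adj["r", "a"], 1)
  expect_equal(adj["a", "b"], 1)

  expect_equal(adjacency_matrix(ontology_dag("solo", NULL)),
               matrix(0, 1, 1, dimnames = list("solo", "solo")))

  dd <- adjacency_matrix(diamond_dag())
  expect_equal(sum(dd[, "c"]), 2)
  expect_equal(sum(dd), sum(lengths(diamond_dag()$parents)))
})

test_that("true_path_closure propagates to all ancestors and is idempotent", {
  dag <- chain_dag()
  a1 <- true_path_closure(data.frame(gene = "g1", term = "b"), dag)
  expect_equal(unname(a1[, "g1"]), c(1, 1, 1))

  a2 <- true_path_closure(data.frame(gene = "g1", term = "r"), dag)
  expect_equal(unname(a2[, "g1"]), c(1, 0, 0))

  # annotating a term plus its ancestor changes nothing (idempotence)
  a3 <- true_path_closure(data.frame(gene = "g1", term = c("b", "a")), dag)
  expect_equal(a3, a1)

  expect_warning(
    a4 <- true_path_closure(
      data.frame(gene = c("g1", "g2"), term = c("b", "nope")), dag),
    "unknown")
  expect_equal(unname(colSums(a4)), c(3, 0))  # g2 kept as all-zero column
  expect_error(
    true_path_closure(data.frame(gene = "g1", term = "nope"), dag,
                      strict = TRUE),
    "unknown term")
})

test_that("closure invariant holds on random DAGs: ancestors of any 1 are 1", {
  for (seed in 1:5) {
    rt <- random_transition(20L, seed)
    set.seed(seed + 100)
    raw <- data.frame(gene = sample(paste0("g", 1:8), 15, replace = TRUE),
                      term = sample(rt$dag$terms, 15, replace = TRUE))
    ann <- true_path_closure(raw, rt$dag)
    ones <- which(ann == 1, arr.ind = TRUE)
    for (r in seq_len(nrow(ones))) {
      anc <- ancestors(rt$dag, rownames(ann)[ones[r, 1L]])
      expect_true(all(ann[anc, ones[r, 2L]] == 1))
    }
    expect_equal(true_path_closure(as.data.frame(as.table(ann))[
      as.vector(ann) == 1, c(2, 1)] |>
        stats::setNames(c("gene", "term")), rt$dag)[, colnames(ann)],
      ann)
  }
})

test_that("read_gaf parses triples, drops NOT rows and excluded evidence", {
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "P1", "GENE1", "", "GO:1", "ref", "EXP", "", "P",
          "", "", "protein", "taxon:9606", "20240101", "DB", "", "",
          sep = "\t"),
    paste("DB", "P2", "GENE2", "NOT", "GO:2", "ref", "EXP", "", "P",
          "", "", "protein", "taxon:9606", "20240101", "DB", "", "",
          sep = "\t"),
    paste("DB", "P3", "GENE3", "", "GO:3", "ref", "IEA", "", "P",
          "", "", "protein", "taxon:9606", "20240101", "DB", "", "",
          sep = "\t")), path)
  gaf <- read_gaf(path)
  expect_equal(gaf$gene, c("GENE1", "GENE3"))
  expect_equal(gaf$term, c("GO:1", "GO:3"))
  gaf2 <- read_gaf(path, exclude_evidence = "IEA")
  expect_equal(gaf2$gene, "GENE1")
  expect_equal(read_gaf(path, id_column = "id")$gene, c("P1", "P3"))
})
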