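#' Build a validated pipeline configuration
#'
#' Collects file paths and all tunable parameters of the annotation
#' optimization pipeline into one serialisable object.
#'
#' @param obo path to the ontology (OBO).
#' @param annotations path to gene annotations (GAF 2.x or gene/term TSV).
#' @param expression path to the genes x samples expression TSV.
#' @param out_dir output directory (created if needed).
#' @param annotation_format `"tsv"` or `"gaf"`.
#' @param gene_sets optional GMT path; when given, a size-filtered and an
#'   optimizer-filtered GMT are written.
#' @param groups optional per-sample two-level label TSV (columns `sample`,
#'   `group`); enables the differential-expression gene filter.
#' @param namespace,include_part_of ontology parsing options, see
#'   [parse_obo()].
#' @param evidence_exclude GAF evidence codes to drop.
#' @param beta,eps,max_iter random-walk parameters, see [steady_state()].
#' @param theta_mode diffusion threshold convention, see
#'   [extend_annotations()].
#' @param k_min,k_max,n_boot consensus parameters, see
#'   [bootstrap_optimize()].
#' @param tau final threshold, see [apply_threshold()].
#' @param alpha_de significance level of the differential-expression filter.
#' @param min_set_size,max_set_size gene-set size bounds, see
#'   [filter_gene_sets()].
#' @param sd_type z-score convention, see [zscore()].
#' @param seed master seed; every stochastic stage derives its stream from
#'   it, so a config reproduces a run bit for bit.
#' @return list of class `run_config`.
#' @export
run_config <- function(obo, annotations, expression, out_dir,
                       annotation_format = c("tsv", "gaf"),
                       gene_sets = NULL, groups = NULL,
                       namespace = "biological_process",
                       include_part_of = FALSE,
                       evidence_exclude = character(),
                       beta = 0.5, eps = 1e-6, max_iter = 100L,
                       theta_mode = "row",
                       k_min = 3L, k_max = 15L, n_boot = 50L, tau = 0.1,
                       alpha_de = 0.05,
                       min_set_size = 15L, max_set_size = 200L,
                       sd_type = "population", seed = 1L) {
  annotation_format <- match.arg(annotation_format)
  stopifnot(beta >= 0, beta <= 1, eps > 0, max_iter >= 1,
            k_min >= 2, k_max >= k_min, n_boot >= 1,
            tau >= 0, tau <= 1, alpha_de > 0, alpha_de <= 1,
            min_set_size <= max_set_size)
  structure(
    list(obo = obo, annotations = annotations, expression = expression,
         out_dir = out_dir, annotation_format = annotation_format,
         gene_sets = gene_sets, groups = groups, namespace = namespace,
         include_part_of = include_part_of,
         evidence_exclude = as.character(evidence_exclude),
         beta = beta, eps = eps, max_iter = as.integer(max_iter),
         theta_mode = theta_mode,
         k_min = as.integer(k_min), k_max = as.integer(k_max),
         n_boot = as.integer(n_boot), tau = tau, alpha_de = alpha_de,
         min_set_size = as.integer(min_set_size),
         max_set_size = as.integer(max_set_size),
         sd_type = sd_type, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose fields are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, args)
}

#' Run the full annotation-optimization pipeline
#'
#' Normalisation, optional differential-expression filtering, true-path
#' closure, information content and Lin similarity, transition matrix,
#' downward random walk, probabilistic extension, consensus bootstrap
#' filtering, and final thresholding. Artifacts are written under
#' `config$out_dir`: the extended matrix, the final and thresholded
#' optimized matrices, per-gene filter scores, optional filtered GMT files,
#' and a JSON manifest of every effective parameter.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory objects (`dag`, `extended`,
#'   `final`, `optimized`, `scores`, paths of written artifacts).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (p in c(config$obo, config$annotations, config$expression,
              config$gene_sets, config$groups)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- stage("read expression", read_expression(config$expression))
  say("expression: ", nrow(expr), " genes x ", ncol(expr), " samples")
  expr <- stage("z-score", zscore(expr, sd_type = config$sd_type))

  if (!is.null(config$groups)) {
    gtab <- stage("read groups", {
      g <- utils::read.delim(config$groups, colClasses = "character")
      stats::setNames(g$group, g$sample)[colnames(expr)]
    })
    keep <- stage("differential-expression filter",
                  de_filter(expr, gtab, alpha = config$alpha_de))
    say("differential-expression filter kept ", length(keep), " of ",
        nrow(expr), " genes")
    expr <- expr[keep, , drop = FALSE]
  }

  dag <- stage("parse ontology",
               parse_obo(config$obo, namespace = config$namespace,
                         include_part_of = config$include_part_of))
  say("ontology: ", length(dag$terms), " terms")

  pairs <- stage("read annotations", {
    if (config$annotation_format == "gaf") {
      read_gaf(config$annotations,
               exclude_evidence = config$evidence_exclude)
    } else {
      read_annotation_pairs(config$annotations)
    }
  })
  pairs <- pairs[pairs$gene %in% rownames(expr), , drop = FALSE]
  if (!nrow(pairs)) stop("no annotations overlap the expression genes")

  a0 <- stage("true-path closure", {
    closed <- true_path_closure(pairs, dag)
    # align columns with the expression gene order; unannotated genes stay
    # as all-zero columns
    full <- matrix(0, length(dag$terms), nrow(expr),
                   dimnames = list(dag$terms, rownames(expr)))
    full[, colnames(closed)] <- closed
    full
  })

  ic <- stage("information content", information_content(a0, dag))
  ssm <- stage("similarity matrix", similarity_matrix(ic, dag))
  tm <- stage("transition matrix",
              transition_matrix(ssm, adjacency_matrix(dag)))
  rs <- stage("steady state",
              steady_state(tm, beta = config$beta, eps = config$eps,
                           max_iter = config$max_iter))
  say("random walk converged in ", rs$iterations, " iterations")
  extended <- stage("annotation extension",
                    extend_annotations(a0, rs, theta_mode = config$theta_mode))

  final <- stage("consensus bootstrap optimization",
                 bootstrap_optimize(extended, expr,
                                    k_min = config$k_min,
                                    k_max = config$k_max,
                                    n_boot = config$n_boot,
                                    seed = config$seed))
  optimized <- apply_threshold(final, tau = config$tau)
  scores <- gene_filter_scores(a0, optimized)

  paths <- list(
    extended = file.path(config$out_dir, "annotation_matrix_extended.tsv"),
    final = file.path(config$out_dir, "annotation_matrix_final.tsv"),
    optimized = file.path(config$out_dir, "annotation_matrix_optimized.tsv"),
    scores = file.path(config$out_dir, "gene_filter_scores.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_matrix_tsv(extended, paths$extended, id_header = "term")
  write_matrix_tsv(final, paths$final, id_header = "term")
  write_matrix_tsv(optimized, paths$optimized, id_header = "term")
  utils::write.table(
    data.frame(gene = names(scores), filter_score = unname(scores)),
    paths$scores, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$gene_sets)) {
    sets <- stage("read gene sets", read_gmt(config$gene_sets))
    sets <- filter_gene_sets(sets, config$min_set_size, config$max_set_size,
                             universe = rownames(expr))
    say(length(sets), " gene set(s) pass the size filter")
    # a gene is dropped from every set when the optimizer removed all of
    # its original annotations
    removed <- names(scores)[!is.na(scores) & scores == 1]
    filtered <- lapply(sets, setdiff, removed)
    paths$gene_sets_filtered <- file.path(config$out_dir,
                                          "gene_sets_filtered.gmt")
    write_gmt(filtered, paths$gene_sets_filtered)
  }

  manifest <- c(unclass(config),
                list(n_genes = nrow(expr), n_samples = ncol(expr),
                     n_terms = length(dag$terms),
                     walk_iterations = rs$iterations))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(dag = dag, extended = extended, final = final,
                 optimized = optimized, scores = scores, paths = paths))
}

#' Write a complete synthetic study to disk
#'
#' Generates a synthetic DAG, planted annotation truth and expression
#' matrix, and writes them in the formats the pipeline reads (OBO, GAF,
#' expression TSV, GMT of leaf-term gene sets, truth tables). Convenient
#' for demos and round-trip tests.
#'
#' @param dir output directory.
#' @param levels,branching,cross_p DAG shape, see [generate_dag()].
#' @param n_genes,k_true,p_inconsistent,annot_prob truth parameters, see
#'   [generate_truth()].
#' @param n_samples,effect,noise_sd expression parameters, see
#'   [generate_expression()].
#' @param seed master seed.
#' @return invisibly, list with the `synthetic_truth`, the expression
#'   matrix, and the written file paths.
#' @export
simulate_study <- function(dir, levels = 3L, branching = 3L, cross_p = 0,
                           n_genes = 200L, k_true = 3L,
                           p_inconsistent = 0.2, annot_prob = 0.5,
                           n_samples = 40L, effect = 2, noise_sd = 1,
                           seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- generate_dag(levels, branching, cross_p,
                      seed = child_seed(seed, 1L))
  truth <- generate_truth(dag, n_genes, k_true, p_inconsistent,
                          seed = child_seed(seed, 2L),
                          annot_prob = annot_prob)
  expr <- generate_expression(truth$cluster_labels, n_samples,
                              effect = effect, noise_sd = noise_sd,
                              seed = child_seed(seed, 3L))
  paths <- list(obo = file.path(dir, "ontology.obo"),
                gaf = file.path(dir, "annotations.gaf"),
                annotations = file.path(dir, "annotations.tsv"),
                expression = file.path(dir, "expression.tsv"),
                gene_sets = file.path(dir, "gene_sets.gmt"),
                truth = file.path(dir, "planted_annotations.tsv"))
  write_obo(dag, paths$obo)
  write_gaf(truth$leaf_pairs, paths$gaf)
  utils::write.table(truth$leaf_pairs[, c("gene", "term")],
                     paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(expr, paths$expression, id_header = "gene")
  sets <- split(truth$leaf_pairs$gene, truth$leaf_pairs$term)
  write_gmt(sets, paths$gene_sets)
  utils::write.table(truth$leaf_pairs, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(truth = truth, expression = expr, paths = paths))
}
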