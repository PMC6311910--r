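#' Read gene sets from a GMT file
#'
#' @param path GMT file: tab-separated lines `name<TAB>description<TAB>gene...`.
#' @return named list of character gene vectors, in file order, with the
#'   descriptions kept as attribute `descriptions`. Duplicate genes within
#'   a set are removed with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(stats::setNames(list(), character()),
                     descriptions = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short)) stop("malformed GMT line ", which(short)[1L],
                       ": fewer than 3 tab-separated fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  n_dup <- sum(vapply(sets, function(g) length(g) - length(unique(g)),
                      integer(1L)))
  if (n_dup > 0L) {
    warning("removed ", n_dup, " duplicate gene(s) within sets")
    sets <- lapply(sets, unique)
  }
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1L), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @param descriptions optional per-set description (recycled; default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions)) descriptions <- "na"
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size
#'
#' @param sets named list of gene sets.
#' @param min_size,max_size inclusive size bounds.
#' @param universe optional gene universe (e.g. measured genes); sizes are
#'   computed after intersecting each set with it, and the kept sets are
#'   returned intersected.
#' @return filtered (and possibly intersected) named list.
#' @export
filter_gene_sets <- function(sets, min_size = 15L, max_size = 200L,
                             universe = NULL) {
  if (min_size > max_size) stop("min_size must not exceed max_size")
  eff <- if (is.null(universe)) sets else lapply(sets, intersect, universe)
  sizes <- lengths(eff)
  eff[sizes >= min_size & sizes <= max_size]
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column.
#'
#' @param path TSV file.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a numeric matrix as TSV with row and column headers
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_header header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, id_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Read gene-term annotation pairs from TSV
#'
#' @param path two-column TSV with a header naming columns `gene` and
#'   `term` (in either order).
#' @return data frame with character columns `gene` and `term`.
#' @export
read_annotation_pairs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("gene", "term") %in% names(df))) {
    stop("annotation TSV needs 'gene' and 'term' columns")
  }
  df[, c("gene", "term")]
}

#' Write an ontology DAG as a minimal OBO document
#'
#' @param dag an [ontology_dag].
#' @param path output file.
#' @param namespace namespace recorded for every term.
#' @export
write_obo <- function(dag, path, namespace = "biological_process") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (tm in dag$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", tm),
                 paste0("name: ", tm),
                 paste0("namespace: ", namespace),
                 paste0("is_a: ", dag$parents[[tm]]),
                 ""), con)
  }
  invisible(path)
}

#' Write gene-term pairs as a minimal GAF 2.2 file
#'
#' @param pairs data frame with columns `gene` and `term` (optional
#'   `evidence`, default `"EXP"`).
#' @param path output file.
#' @export
write_gaf <- function(pairs, path) {
  ev <- if ("evidence" %in% names(pairs)) pairs$evidence else "EXP"
  rows <- paste("SYNDB", pairs$gene, pairs$gene, "", pairs$term, "SYN:0000001",
                ev, "", "P", "", "", "protein", "taxon:0000", "20260101",
                "SYNDB", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
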