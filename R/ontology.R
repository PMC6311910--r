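#' Construct a rooted ontology DAG
#'
#' Builds the in-memory representation of a Gene Ontology-style directed
#' acyclic graph from a term list and a set of parent edges. The term order
#' given here is frozen: every matrix derived from the DAG (adjacency,
#' similarity, transition, annotation) uses it for its rows and columns.
#'
#' @param terms character vector of unique term identifiers.
#' @param parent_edges two-column character matrix or data frame of
#'   `(parent, child)` pairs over `is_a`-style relations. May be empty for a
#'   single-term ontology.
#' @return An object of class `ontology_dag`: a list with elements `terms`,
#'   `parents` (named list, per-term parent identifiers), `children`,
#'   `root` and `topo` (a topological order, ancestors first).
#' @details The graph must be acyclic and single-rooted; a cycle aborts with
#'   an error naming one edge on the cycle. Because every non-root term has at
#'   least one parent, single-rootedness guarantees all terms are reachable
#'   from the root.
#' @seealso [parse_obo()] which builds a DAG from an OBO document,
#'   [generate_dag()] for synthetic DAGs.
#' @export
ontology_dag <- function(terms, parent_edges) {
  terms <- as.character(terms)
  if (length(terms) < 1L) stop("ontology must contain at least one term")
  if (anyDuplicated(terms)) stop("duplicate term identifiers")

  pe <- if (is.null(parent_edges) || length(parent_edges) == 0L) {
    matrix(character(), ncol = 2L)
  } else {
    as.matrix(parent_edges)
  }
  if (ncol(pe) != 2L) stop("parent_edges must have two columns (parent, child)")
  mode(pe) <- "character"
  pe <- unique(pe)
  unknown <- setdiff(c(pe), terms)
  if (length(unknown)) {
    stop("edge endpoint(s) not in term list: ", paste(unknown, collapse = ", "))
  }
  self_loop <- pe[, 1L] == pe[, 2L]
  if (any(self_loop)) {
    stop("cycle detected: edge ", pe[self_loop, 1L][1L], " -> ",
         pe[self_loop, 2L][1L])
  }

  fac <- function(x) factor(x, levels = terms)
  parents <- lapply(split(pe[, 1L], fac(pe[, 2L])), as.character)
  children <- lapply(split(pe[, 2L], fac(pe[, 1L])), as.character)

  # Kahn's algorithm: topological order doubles as the acyclicity check.
  indeg <- lengths(parents)
  queue <- terms[indeg == 0L]
  topo <- character(0L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    topo <- c(topo, v)
    for (w in children[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(topo) < length(terms)) {
    leftover <- setdiff(terms, topo)
    child <- leftover[1L]
    par <- intersect(parents[[child]], leftover)[1L]
    stop("cycle detected: edge ", par, " -> ", child)
  }

  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root, found ", length(roots), ": ",
         paste(utils::head(roots, 5L), collapse = ", "))
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         root = roots, topo = topo),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("ontology_dag:", length(x$terms), "terms,", n_edges,
      "is_a edges, root", x$root, "\n")
  invisible(x)
}

#' Leaf terms of a DAG
#'
#' @param dag an [ontology_dag].
#' @return character vector of terms with no children, in term order.
#' @export
dag_leaves <- function(dag) {
  dag$terms[lengths(dag$children) == 0L]
}

#' Proper ancestors of a term
#'
#' All terms reachable from `term` by following parent (`is_a`) edges,
#' excluding the term itself.
#'
#' @param dag an [ontology_dag].
#' @param term a term identifier present in `dag`.
#' @return character vector of ancestor identifiers (unordered set).
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  seen <- character(0L)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  seen
}

# t x t logical matrix: entry (p, q) is TRUE when p is an ancestor of q
# (inclusive = TRUE also marks p == q). Computed in one topological sweep.
ancestor_matrix <- function(dag, inclusive = FALSE) {
  t_n <- length(dag$terms)
  idx <- stats::setNames(seq_len(t_n), dag$terms)
  anc <- matrix(FALSE, t_n, t_n, dimnames = list(dag$terms, dag$terms))
  for (q in dag$topo) {
    j <- idx[[q]]
    for (p in dag$parents[[q]]) {
      i <- idx[[p]]
      anc[, j] <- anc[, j] | anc[, i]
      anc[i, j] <- TRUE
    }
  }
  if (inclusive) diag(anc) <- TRUE
  anc
}

#' Parent-child adjacency matrix of a DAG
#'
#' @param dag an [ontology_dag].
#' @return a t x t numeric 0/1 matrix with entry `(p, q) = 1` exactly when
#'   `q` is a direct child of `p`; row and column names are the term order.
#' @export
adjacency_matrix <- function(dag) {
  t_n <- length(dag$terms)
  adj <- matrix(0, t_n, t_n, dimnames = list(dag$terms, dag$terms))
  idx <- stats::setNames(seq_len(t_n), dag$terms)
  for (q in dag$terms) {
    for (p in dag$parents[[q]]) adj[idx[[p]], idx[[q]]] <- 1
  }
  adj
}

#' Close raw annotations under the true-path rule
#'
#' A gene annotated with a term is implicitly annotated with every ancestor
#' of that term; this function materialises that closure as a binary
#' term x gene matrix.
#'
#' @param raw_annotations data frame (or two-column object) with columns
#'   `gene` and `term`; one row per curated annotation.
#' @param dag an [ontology_dag]; rows of the result follow its term order.
#' @param strict if `TRUE`, an annotation to a term absent from `dag` is an
#'   error; otherwise such rows are skipped with a warning.
#' @param drop_unannotated drop genes whose every annotation was skipped
#'   (default keeps them as all-zero columns).
#' @return numeric 0/1 matrix, terms x genes, closed under the true-path
#'   rule; gene columns follow first appearance in `raw_annotations`.
#' @export
true_path_closure <- function(raw_annotations, dag, strict = FALSE,
                              drop_unannotated = FALSE) {
  raw <- as.data.frame(raw_annotations)
  if (!all(c("gene", "term") %in% names(raw))) {
    if (ncol(raw) >= 2L) names(raw)[1:2] <- c("gene", "term")
    else stop("raw_annotations needs columns 'gene' and 'term'")
  }
  raw$gene <- as.character(raw$gene)
  raw$term <- as.character(raw$term)

  known <- raw$term %in% dag$terms
  if (!all(known)) {
    bad <- unique(raw$term[!known])
    if (strict) stop("unknown term(s): ", paste(bad, collapse = ", "))
    warning("skipping ", sum(!known), " annotation(s) to ", length(bad),
            " unknown term(s)")
  }
  genes <- unique(raw$gene)
  raw <- raw[known, , drop = FALSE]
  if (drop_unannotated) genes <- intersect(genes, unique(raw$gene))
  if (!length(genes)) stop("no genes left after filtering")

  t_n <- length(dag$terms)
  a0 <- matrix(0, t_n, length(genes), dimnames = list(dag$terms, genes))
  if (nrow(raw)) {
    a0[cbind(match(raw$term, dag$terms), match(raw$gene, genes))] <- 1
  }
  anc <- ancestor_matrix(dag, inclusive = TRUE)
  closed <- (anc %*% a0) > 0
  storage.mode(closed) <- "double"
  closed
}

#' Parse an OBO 1.2/1.4 document into an ontology DAG
#'
#' Reads `[Term]` stanzas, keeps one namespace, drops obsolete terms, and
#' wires `is_a` (and optionally `part_of`) relations whose two endpoints
#' survive filtering. When more than one root remains, a virtual root is
#' synthesised above them (with a message) so the result is single-rooted.
#'
#' @param x path to an OBO file, or a character vector of its lines (a
#'   single string containing newlines is split).
#' @param namespace ontology namespace to keep (default
#'   `"biological_process"`).
#' @param include_part_of also treat `relationship: part_of` as a parent
#'   edge (default `FALSE`: `is_a` only).
#' @param virtual_root identifier used when a virtual root must be added.
#' @return an [ontology_dag].
#' @export
parse_obo <- function(x, namespace = "biological_process",
                      include_part_of = FALSE,
                      virtual_root = "VIRTUAL:ROOT") {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character(0L), part_of = character(0L),
                  obsolete = FALSE, namespace = NA_character_)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # another stanza type ends the term
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    ln <- sub("\\s*!.*$", "", ln)  # trailing comments
    if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (grepl("^is_a:", ln)) {
      cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
      cur$part_of <- c(cur$part_of,
                       trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found")

  keep <- vapply(terms, function(tm) {
    !tm$obsolete && (is.na(tm$namespace) || tm$namespace == namespace)
  }, logical(1L))
  terms <- terms[keep]
  if (!length(terms)) stop("no terms in namespace '", namespace, "'")

  ids <- names(terms)
  edges <- do.call(rbind, lapply(terms, function(tm) {
    parents <- tm$is_a
    if (include_part_of) parents <- c(parents, tm$part_of)
    parents <- intersect(parents, ids)
    if (length(parents)) cbind(parent = parents, child = tm$id) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)

  has_parent <- ids %in% edges[, 2L]
  roots <- ids[!has_parent]
  if (length(roots) > 1L) {
    message("synthesising virtual root '", virtual_root, "' over ",
            length(roots), " namespace roots")
    ids <- c(virtual_root, ids)
    edges <- rbind(cbind(parent = virtual_root, child = roots), edges)
  }
  ontology_dag(ids, edges)
}

#' Read gene annotations from a GAF 2.x file
#'
#' @param path GAF file path; comment lines starting with `!` are ignored.
#' @param exclude_evidence evidence codes to drop (e.g. `"IEA"`); default
#'   keeps all.
#' @param id_column `"symbol"` (GAF column 3, default) or `"id"` (column 2)
#'   as the gene identifier.
#' @return data frame with columns `gene`, `term`, `evidence`; rows with a
#'   `NOT` qualifier are dropped.
#' @export
read_gaf <- function(path, exclude_evidence = character(),
                     id_column = c("symbol", "id")) {
  id_column <- match.arg(id_column)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene = character(), term = character(),
                      evidence = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 7L
  if (any(short)) stop("malformed GAF line ", which(short)[1L])
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  out <- data.frame(gene = if (id_column == "symbol") col(3L) else col(2L),
                    term = col(5L), evidence = col(7L),
                    qualifier = col(4L))
  out <- out[!grepl("(^|\\|)NOT($|\\|)", out$qualifier), ]
  out <- out[!out$evidence %in% exclude_evidence, c("gene", "term", "evidence")]
  rownames(out) <- NULL
  out
}
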