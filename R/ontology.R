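#' Construct an ontology DAG
#'
#' An ontology is a set of terms connected by `is_a` edges, each term
#' belonging to one namespace (e.g. `biological_process`,
#' `molecular_function`, `cellular_component`). Each namespace must contain
#' exactly one root (a term with no parents), every term must reach its
#' namespace root, and the graph must be acyclic. Violations are errors:
#' a cyclic or rootless file is rejected outright rather than silently
#' truncated.
#'
#' @param terms A data frame with columns `term_id` (character, unique),
#'   `name` (character), `namespace` (character) and `parents` (list column
#'   of character vectors; `is_a` parents, empty for a root).
#' @return An object of class `ontology`: a list with `terms` (tibble as
#'   above), `parents` (named list for fast lookup) and `roots` (named
#'   character vector, namespace -> root term id).
#' @examples
#' onto <- ontology(tibble::tibble(
#'   term_id = c("T:1", "T:2"), name = c("root", "child"),
#'   namespace = "biological_process",
#'   parents = list(character(), "T:1")))
#' ontology_ancestors(onto, "T:2")
#' @export
ontology <- function(terms) {
  terms <- tibble::as_tibble(terms)
  required <- c("term_id", "name", "namespace", "parents")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0) {
    abort(paste0("`terms` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(terms$term_id)) {
    dup <- unique(terms$term_id[duplicated(terms$term_id)])
    abort(paste0("duplicate term id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  parents <- setNames(lapply(terms$parents, as.character), terms$term_id)
  unknown <- setdiff(unlist(parents, use.names = FALSE), terms$term_id)
  if (length(unknown) > 0) {
    abort(paste0("parent id(s) not present in the ontology: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ns <- setNames(terms$namespace, terms$term_id)
  for (id in terms$term_id) {
    bad <- parents[[id]][ns[parents[[id]]] != ns[[id]]]
    if (length(bad) > 0) {
      abort(paste0("term ", id, " has is_a parent(s) in a different namespace: ",
                   paste(bad, collapse = ", ")))
    }
  }
  .check_acyclic(parents)
  roots <- vapply(split(terms$term_id, terms$namespace), function(ids) {
    r <- ids[lengths(parents[ids]) == 0L]
    if (length(r) != 1L) {
      abort(paste0("namespace must have exactly one root, found ",
                   length(r), ": ", paste(r, collapse = ", ")))
    }
    r
  }, character(1))
  structure(list(terms = terms, parents = parents, roots = roots),
            class = "ontology")
}

# depth-first cycle check over is_a edges; cycles are a hard load error
.check_acyclic <- function(parents) {
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  visit <- function(id) {
    s <- state[[id]]
    if (!is.null(s)) {
      if (s == 1L) abort(paste0("cycle detected through term ", id))
      return(invisible())
    }
    state[[id]] <- 1L
    for (p in parents[[id]]) visit(p)
    state[[id]] <- 2L
  }
  for (id in names(parents)) visit(id)
  invisible()
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", nrow(x$terms), " terms, ",
      length(x$roots), " namespace(s): ",
      paste(names(x$roots), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ancestors of a term (reflexive transitive closure over is_a edges)
#'
#' Returns the term itself together with every term reachable by following
#' `is_a` edges toward the root. The closure is reflexive so that a gene
#' annotated to a term counts for that term in enrichment; it always
#' contains the namespace root.
#'
#' @param onto An [ontology()].
#' @param term_id A single term accession present in `onto`.
#' @return Character vector of term accessions (unordered set).
#' @export
ontology_ancestors <- function(onto, term_id) {
  stopifnot(inherits(onto, "ontology"))
  if (!term_id %in% names(onto$parents)) {
    abort(paste0("unknown term id: ", term_id))
  }
  seen <- new.env(parent = emptyenv())
  stack <- term_id
  while (length(stack) > 0) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (is.null(seen[[id]])) {
      seen[[id]] <- TRUE
      stack <- c(stack, onto$parents[[id]])
    }
  }
  ls(seen)
}

# ancestor sets for every term at once, by dynamic programming in
# topological order (parents before children); used by the closure step
.all_ancestors <- function(onto) {
  ids <- names(onto$parents)
  anc <- vector("list", length(ids))
  names(anc) <- ids
  done <- new.env(parent = emptyenv())
  for (start in ids) {
    stack <- start
    while (length(stack) > 0) {
      id <- stack[[length(stack)]]
      if (!is.null(done[[id]])) {
        stack <- stack[-length(stack)]
        next
      }
      todo <- onto$parents[[id]][vapply(onto$parents[[id]],
                                        function(p) is.null(done[[p]]),
                                        logical(1))]
      if (length(todo) > 0) {
        stack <- c(stack, todo)
      } else {
        anc[[id]] <- unique(c(id, unlist(anc[onto$parents[[id]]],
                                         use.names = FALSE)))
        done[[id]] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
  }
  anc
}

#' Back-propagate gene annotations to the root
#'
#' Extends each gene's direct term annotations with all ancestor terms up
#' to the namespace root, the closure step applied before counting genes
#' per term in over-representation testing. The result is marked closed
#' (attribute `closed`); propagating an already-closed map is the identity.
#'
#' @param onto An [ontology()].
#' @param annotations A data frame with columns `gene` and `term_id`
#'   (direct annotations; duplicates allowed, collapsed on return).
#' @return A tibble with columns `gene`, `term_id`, closed under `is_a`
#'   edges, sorted by gene then term, with attribute `closed = TRUE`.
#' @examples
#' onto <- ontology(tibble::tibble(
#'   term_id = c("T:1", "T:2", "T:3"), name = c("root", "mid", "leaf"),
#'   namespace = "biological_process",
#'   parents = list(character(), "T:1", "T:2")))
#' propagate_annotations(onto, tibble::tibble(gene = "Pla2g7", term_id = "T:3"))
#' @export
propagate_annotations <- function(onto, annotations) {
  stopifnot(inherits(onto, "ontology"))
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("gene", "term_id") %in% names(annotations))) {
    abort("`annotations` must have columns `gene` and `term_id`")
  }
  if (nrow(annotations) == 0) {
    out <- tibble::tibble(gene = character(), term_id = character())
    attr(out, "closed") <- TRUE
    return(out)
  }
  bad <- !annotations$term_id %in% names(onto$parents)
  if (any(bad)) {
    pairs <- paste0(annotations$gene[bad], " -> ", annotations$term_id[bad])
    abort(paste0("annotation(s) reference term(s) absent from the ontology: ",
                 paste(head(unique(pairs), 5), collapse = "; ")))
  }
  anc <- .all_ancestors(onto)
  by_gene <- split(annotations$term_id, annotations$gene)
  closed <- lapply(by_gene, function(terms) {
    unique(unlist(anc[unique(terms)], use.names = FALSE))
  })
  out <- tibble::tibble(
    gene = rep(names(closed), lengths(closed)),
    term_id = unlist(closed, use.names = FALSE)
  )
  out <- dplyr::arrange(out, .data$gene, .data$term_id)
  attr(out, "closed") <- TRUE
  out
}

#' Is an annotation map closed under back-propagation?
#' @param annotations An annotation data frame.
#' @return `TRUE` if the map carries the `closed` attribute set by
#'   [propagate_annotations()].
#' @export
is_closed <- function(annotations) {
  isTRUE(attr(annotations, "closed"))
}
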