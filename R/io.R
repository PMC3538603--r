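# Plain-text formats: expression TSV (probe_id + one column per sample),
# OBO subset, 2-column annotation TSV, GMT, long-format Ct TSV, Newick.
# Readers fail loudly with the offending line; writers round-trip.

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row (`probe_id` then sample labels) and one row per
#' probe; values are log2 intensities.
#'
#' @param path File path.
#' @return Expression tibble.
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "probe_id") names(expr)[1] <- "probe_id"
  samples <- setdiff(names(expr), "probe_id")
  for (s in samples) {
    if (!is.numeric(expr[[s]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(expr[[s]]))))[1]
      abort(paste0("non-numeric value in column ", s, " at data line ", bad))
    }
  }
  .check_expression(expr)
}

#' Write a log2 expression matrix to TSV
#' @param expr Expression tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(.check_expression(expr), path, progress = FALSE)
  invisible(path)
}

#' Read an OBO-subset ontology file
#'
#' Recognises `[Term]` stanzas and the keys `id:`, `name:`, `namespace:`
#' and `is_a:` (taking the id portion before any `!` comment). All other
#' keys and stanza types are ignored; terms marked `is_obsolete: true`
#' are dropped. Richer OBO semantics (`relationship:` edges, subsets,
#' intersections) are deliberately not interpreted: only `is_a` edges
#' feed back-propagation.
#'
#' @param path File path.
#' @return An [ontology()].
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    tibble::tibble(term_id = cur$id,
                   name = cur$name %||% "",
                   namespace = cur$namespace %||% "unknown",
                   parents = list(cur$parents))
  }
  out <- list()
  in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      out[[length(out) + 1L]] <- flush(cur)
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      out[[length(out) + 1L]] <- flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (grepl("^id:", ln)) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (grepl("^name:", ln)) {
        cur$name <- trimws(sub("^name:", "", ln))
      } else if (grepl("^namespace:", ln)) {
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      } else if (grepl("^is_a:", ln)) {
        target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (!nzchar(target)) abort(paste0("empty is_a target at line ", i))
        cur$parents <- c(cur$parents, target)
      } else if (grepl("^is_obsolete:\\s*true", ln)) {
        cur$obsolete <- TRUE
      }
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) abort("no [Term] stanzas found")
  # edges to dropped (obsolete) terms would dangle; remove them before
  # DAG validation so obsoleting a parent does not reject the file
  out$parents <- lapply(out$parents, intersect, out$term_id)
  ontology(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ontology as an OBO subset
#' @param onto An [ontology()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(onto$terms))) {
    writeLines(c("", "[Term]",
                 paste0("id: ", onto$terms$term_id[i]),
                 paste0("name: ", onto$terms$name[i]),
                 paste0("namespace: ", onto$terms$namespace[i]),
                 paste0("is_a: ", onto$terms$parents[[i]],
                        recycle0 = TRUE)), con)
  }
  invisible(path)
}

#' Read gene-to-term annotations from a 2-column TSV
#'
#' Columns are gene symbol and term accession; `#` comment lines are
#' allowed; duplicate pairs are collapsed.
#'
#' @param path File path.
#' @return Tibble `gene`, `term_id`.
#' @export
read_annotations_tsv <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    abort(paste0("expected 2 tab-separated fields at line ", idx[nf != 2][1]))
  }
  out <- tibble::tibble(gene = vapply(parts, `[[`, "", 1),
                        term_id = vapply(parts, `[[`, "", 2))
  dplyr::distinct(out)
}

#' Write gene-to-term annotations to TSV
#' @param annotations Tibble `gene`, `term_id`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  readr::write_tsv(tibble::as_tibble(annotations)[, c("gene", "term_id")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-separated (at
#' least 3 fields).
#'
#' @param path File path.
#' @return Long tibble `set`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(paste0("GMT line with fewer than 3 fields at line ", idx[nf < 3][1]))
  }
  dplyr::bind_rows(lapply(parts, function(p) {
    tibble::tibble(set = p[1], description = p[2], gene = p[-(1:2)])
  }))
}

#' Write gene sets to a GMT file
#' @param genesets Long tibble `set`, `description`, `gene`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  genesets <- tibble::as_tibble(genesets)
  sets <- split(genesets, factor(genesets$set, levels = unique(genesets$set)))
  lines <- vapply(sets, function(s) {
    paste(c(s$set[1], s$description[1] %||% "", s$gene), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a long-format Ct table from TSV
#' @param path File path (columns `condition`, `gene`, `replicate`,
#'   `ct`).
#' @return Ct tibble.
#' @export
read_ct_tsv <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  .check_ct(ct)
}

#' Write a long-format Ct table to TSV
#' @param ct Ct tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ct_tsv <- function(ct, path) {
  readr::write_tsv(.check_ct(ct), path, progress = FALSE)
  invisible(path)
}

#' Write an enrichment result table to TSV
#'
#' The list-column of member study genes is comma-joined.
#'
#' @param results A [go_enrichment()] or [kegg_enrichment()] tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  out <- tibble::as_tibble(results)
  if ("genes" %in% names(out)) {
    out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a UPGMA tree as a merge-list TSV
#' @param tree An [upgma_cluster()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_linkage_tsv <- function(tree, path) {
  readr::write_tsv(tidy(tree), path, progress = FALSE)
  invisible(path)
}

#' Write a UPGMA tree in Newick format
#'
#' Branch lengths follow the ultrametric dendrogram convention: each
#' leaf sits at half its merge distance below the merge node, so sister
#' branch lengths are half the merge-distance increments.
#'
#' @param tree An [upgma_cluster()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
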