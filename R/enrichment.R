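#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more annotated genes among `n` drawn
#' without replacement from a background of `N` genes of which `K` are
#' annotated: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed in
#' log space (log-gamma factorials, tail summed from `k` with a
#' log-sum-exp), so it does not underflow at genome scale.
#'
#' @param N Background size.
#' @param K Annotated genes in the background.
#' @param n Study-set size (within the background).
#' @param k Annotated genes in the study set.
#' @return The upper-tail probability, in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3) # 11/42
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      abort("N, K, n, k must be single non-negative integers")
    }
  }
  if (K > N || n > N) abort("count invariants violated: need K <= N and n <= N")
  if (k > min(K, n)) abort("count invariants violated: need k <= min(K, n)")
  if (k == 0) return(1)
  i <- seq(k, min(K, n))
  i <- i[i >= max(0, n - (N - K))] # support of the distribution
  if (length(i) == 0) return(0)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logp)
  p <- exp(mx + log(sum(exp(logp - mx))))
  min(p, 1)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' Adjusted value for the i-th smallest of `m` p-values:
#' `q_(i) = min over j >= i of (p_(j) * m / j)`, capped at 1 and mapped
#' back to input order. A hypothesis is rejected when `q <= alpha`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level for the rejection flags (default 0.05).
#' @return Tibble with columns `p`, `q`, `significant`, in input order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.04, 0.03, 0.02))
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p = numeric(), q = numeric(), significant = logical()))
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(raw))))
  q <- numeric(m)
  q[o] <- q_sorted
  tibble::tibble(p = p, q = q, significant = q <= alpha)
}

# shared counting + testing core for GO and flat-set enrichment.
# `membership`: tibble(gene, id) of gene-to-term/set assignments, already
# restricted to the background. BH is applied within `bh_group`.
.enrich_core <- function(study, background, membership, alpha, bh_group) {
  study <- unique(study)
  background <- unique(background)
  if (length(background) == 0) abort("background gene set is empty")
  if (length(study) == 0) abort("study gene set is empty")
  outside <- setdiff(study, background)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " study gene(s) absent from the background ",
                "were dropped: ", paste(head(outside, 5), collapse = ", ")))
    study <- intersect(study, background)
    if (length(study) == 0) abort("no study genes remain within the background")
  }
  N <- length(background)
  n <- length(study)
  counts <- membership |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene),
      k = dplyr::n_distinct(.data$gene[.data$gene %in% .env$study]),
      genes = list(sort(intersect(unique(.data$gene), .env$study))),
      .groups = "drop")
  counts <- dplyr::filter(counts, .data$K >= 1)
  counts$N <- N
  counts$n <- n
  counts$p <- purrr::pmap_dbl(
    list(counts$K, counts$k),
    function(K, k) hypergeom_upper_tail(N, K, n, k))
  grp <- if (is.null(bh_group)) {
    rep("all", nrow(counts))
  } else {
    bh_group[match(counts$id, names(bh_group))]
  }
  counts$q <- NA_real_
  counts$significant <- NA
  for (g in unique(grp)) {
    sel <- grp == g
    adj <- benjamini_hochberg(counts$p[sel], alpha)
    counts$q[sel] <- adj$q
    counts$significant[sel] <- adj$significant
  }
  dplyr::arrange(counts, .data$q, .data$p, .data$id)
}

#' Gene Ontology over-representation test
#'
#' Tests every GO term for over-representation of the study genes within
#' the background, using the upper-tail hypergeometric probability on
#' back-propagated annotations. Annotations are closed over `is_a` edges
#' internally when not already closed (see [propagate_annotations()]).
#' Benjamini-Hochberg correction is applied within each namespace
#' separately (each namespace is its own ontology with its own root);
#' terms annotating no background gene are not tested and do not count
#' toward the correction. All tested terms are returned, significant or
#' not, so results can be re-thresholded downstream.
#'
#' @param study Character vector of study gene symbols (e.g. the
#'   differentially expressed genes). Genes outside the background are
#'   dropped with a warning.
#' @param background Character vector of background gene symbols (e.g.
#'   genes whose expression range passes [select_background()]).
#' @param onto An [ontology()].
#' @param annotations Gene-to-term data frame (`gene`, `term_id`), direct
#'   or already closed.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return Tibble sorted by `q` then `p`: `term_id`, `name`, `namespace`,
#'   `N`, `K`, `n`, `k`, `p`, `q`, `significant`, and a list-column
#'   `genes` of the study genes annotated to the term.
#' @export
go_enrichment <- function(study, background, onto, annotations, alpha = 0.05) {
  stopifnot(inherits(onto, "ontology"))
  if (!is_closed(annotations)) {
    annotations <- propagate_annotations(onto, annotations)
  }
  ann <- dplyr::filter(tibble::as_tibble(annotations),
                       .data$gene %in% unique(background))
  membership <- tibble::tibble(gene = ann$gene, id = ann$term_id)
  ns <- setNames(onto$terms$namespace, onto$terms$term_id)
  res <- .enrich_core(study, background, membership, alpha, bh_group = ns)
  info <- onto$terms[match(res$id, onto$terms$term_id), ]
  tibble::tibble(
    term_id = res$id, name = info$name, namespace = info$namespace,
    N = res$N, K = res$K, n = res$n, k = res$k,
    p = res$p, q = res$q, significant = res$significant,
    genes = res$genes)
}

#' Flat gene-set (KEGG-style pathway) over-representation test
#'
#' Same statistics as [go_enrichment()] applied to flat gene sets such as
#' KEGG pathways — no back-propagation step is needed. Sets are
#' intersected with the background; Benjamini-Hochberg correction is
#' applied across all tested sets. Each result carries the study genes
#' inside the set (e.g. the upregulated pathway members to highlight).
#'
#' @inheritParams go_enrichment
#' @param genesets Data frame `set`, `gene` (long format, as returned by
#'   [read_gmt()]; an optional `description` column is carried through).
#' @return Tibble sorted by `q` then `p`: `set`, `description`, `N`, `K`,
#'   `n`, `k`, `p`, `q`, `significant`, list-column `genes`.
#' @export
kegg_enrichment <- function(study, background, genesets, alpha = 0.05) {
  genesets <- tibble::as_tibble(genesets)
  if (!all(c("set", "gene") %in% names(genesets))) {
    abort("`genesets` must have columns `set` and `gene`")
  }
  keep <- genesets$gene %in% unique(background)
  membership <- tibble::tibble(gene = genesets$gene[keep],
                               id = genesets$set[keep])
  res <- .enrich_core(study, background, membership, alpha, bh_group = NULL)
  desc <- if ("description" %in% names(genesets)) {
    genesets$description[match(res$id, genesets$set)]
  } else {
    NA_character_
  }
  tibble::tibble(
    set = res$id, description = desc,
    N = res$N, K = res$K, n = res$n, k = res$k,
    p = res$p, q = res$q, significant = res$significant,
    genes = res$genes)
}

#' Frequency of GO terms among study genes
#'
#' Counts, for every term of one namespace, how many study genes are
#' annotated to it after back-propagation — the numbers behind a GO term
#' frequency pie chart. The namespace root (to which every annotated gene
#' belongs by construction) is excluded from the ranked listing.
#'
#' @inheritParams go_enrichment
#' @param namespace Which namespace to summarise (default
#'   `"biological_process"`).
#' @return Tibble `term_id`, `name`, `n_genes`, sorted by descending
#'   count.
#' @export
go_term_frequency <- function(study, onto, annotations,
                              namespace = "biological_process") {
  stopifnot(inherits(onto, "ontology"))
  if (!namespace %in% names(onto$roots)) {
    abort(paste0("unknown namespace: ", namespace))
  }
  if (!is_closed(annotations)) {
    annotations <- propagate_annotations(onto, annotations)
  }
  ns <- setNames(onto$terms$namespace, onto$terms$term_id)
  ann <- tibble::as_tibble(annotations) |>
    dplyr::filter(.data$gene %in% unique(study),
                  ns[.data$term_id] == namespace,
                  .data$term_id != onto$roots[[namespace]])
  out <- ann |>
    dplyr::distinct(.data$gene, .data$term_id) |>
    dplyr::count(.data$term_id, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$term_id)
  out$name <- onto$terms$name[match(out$term_id, onto$terms$term_id)]
  out[, c("term_id", "name", "n_genes")]
}
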