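# An expression matrix travels as a tibble: `probe_id` plus one numeric
# column per sample, log2 scale (GCRMA-normalized upstream; normalization
# itself is not performed here).

.check_expression <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (!"probe_id" %in% names(expr)) abort("expression table needs a `probe_id` column")
  samples <- setdiff(names(expr), "probe_id")
  if (length(samples) < 2) abort("expression table needs at least 2 sample columns")
  if (anyDuplicated(expr$probe_id)) {
    dup <- unique(expr$probe_id[duplicated(expr$probe_id)])
    abort(paste0("duplicate probe id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(expr[samples])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(!is.finite(vals))) abort("expression values must all be finite")
  expr
}

.check_sample <- function(expr, label) {
  if (!label %in% setdiff(names(expr), "probe_id")) {
    abort(paste0("unknown sample label: ", label))
  }
  invisible(label)
}

#' Classify probes by log2 fold change between two samples
#'
#' Computes, per probe, `delta = treatment - control` (both columns are
#' log2 intensities, so `delta` is the log2 fold change) and calls each
#' probe `up` when `delta >= theta`, `down` when `delta <= -theta`, and
#' `similar` otherwise. Bounds are inclusive: a probe changed by exactly
#' one-fold in log2 at the default `theta = 1` is differential.
#'
#' @param expr Expression tibble (`probe_id` + sample columns, log2).
#' @param control,treatment Sample column names; `delta` is
#'   treatment minus control.
#' @param theta Positive log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @return A tibble of class `fold_change_calls` with columns `probe_id`,
#'   `delta`, `call` (factor up/similar/down), and attributes `control`,
#'   `treatment`, `theta`. Use [glance()] for the up/similar/down counts.
#' @examples
#' expr <- tibble::tibble(probe_id = c("a", "b", "c"),
#'                        Ctr = c(5, 5, 5), C4 = c(6.2, 5.1, 3.5))
#' classify_fold_change(expr, "Ctr", "C4")
#' @export
classify_fold_change <- function(expr, control, treatment, theta = 1) {
  expr <- .check_expression(expr)
  .check_sample(expr, control)
  .check_sample(expr, treatment)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    abort("`theta` must be a single positive number")
  }
  delta <- expr[[treatment]] - expr[[control]]
  call <- dplyr::case_when(delta >= theta ~ "up",
                           delta <= -theta ~ "down",
                           TRUE ~ "similar")
  out <- tibble::tibble(
    probe_id = expr$probe_id,
    delta = delta,
    call = factor(call, levels = c("up", "similar", "down"))
  )
  structure(out, control = control, treatment = treatment, theta = theta,
            class = c("fold_change_calls", class(out)))
}

#' @export
#' @method glance fold_change_calls
glance.fold_change_calls <- function(x, ...) {
  tibble::tibble(
    control = attr(x, "control"),
    treatment = attr(x, "treatment"),
    theta = attr(x, "theta"),
    n_probes = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    n_similar = sum(x$call == "similar")
  )
}

#' Select the background (expressed) probe set for enrichment
#'
#' The background for over-representation testing is restricted to probes
#' whose expression varies across samples: the difference between the
#' lowest and highest sample must be at least `min_range` (default 1 log2,
#' inclusive). With a probe-to-gene map, the gene-level background is
#' every gene with at least one qualifying probe.
#'
#' @param expr Expression tibble.
#' @param min_range Minimum max-minus-min across samples, log2 units.
#' @param probe_gene_map Optional data frame `probe_id`, `gene`; adds a
#'   `gene` column (probes without a mapping get `NA`).
#' @return Tibble `probe_id`, `expr_range` (and `gene` if mapped) for
#'   qualifying probes.
#' @export
select_background <- function(expr, min_range = 1, probe_gene_map = NULL) {
  expr <- .check_expression(expr)
  if (!is.numeric(min_range) || length(min_range) != 1 || min_range < 0) {
    abort("`min_range` must be a single non-negative number")
  }
  vals <- as.matrix(expr[setdiff(names(expr), "probe_id")])
  rng <- apply(vals, 1, max) - apply(vals, 1, min)
  out <- tibble::tibble(probe_id = expr$probe_id, expr_range = rng)
  out <- dplyr::filter(out, .data$expr_range >= min_range)
  if (!is.null(probe_gene_map)) {
    out <- dplyr::left_join(out, tibble::as_tibble(probe_gene_map),
                            by = "probe_id")
  }
  out
}

#' Summarise a pairwise scatter comparison of two samples
#'
#' Reproduces the per-panel numbers of a pairwise scatter plot: the count
#' and percentage of similarly and differentially expressed transcripts at
#' threshold `theta`, and the Pearson correlation of the two expression
#' columns over all probes. Percentages are taken with respect to
#' `total_transcripts`, defaulting to the number of probes in the matrix
#' (the full array, 45,101 probe sets, in the motivating design).
#'
#' @inheritParams classify_fold_change
#' @param total_transcripts Denominator for the percentages; must be at
#'   least the number of probes.
#' @return One-row tibble: `control`, `treatment`, `n_similar`,
#'   `per_similar`, `r`, `n_different`, `per_different`,
#'   `total_transcripts`. `r` is `NA` (with a warning) when either column
#'   has zero variance.
#' @export
scatter_summary <- function(expr, control, treatment, theta = 1,
                            total_transcripts = nrow(expr)) {
  expr <- .check_expression(expr)
  if (total_transcripts < nrow(expr)) {
    abort("`total_transcripts` must be >= the number of probes")
  }
  calls <- classify_fold_change(expr, control, treatment, theta)
  n_diff <- sum(calls$call != "similar")
  n_sim <- nrow(calls) - n_diff
  x <- expr[[control]]
  y <- expr[[treatment]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance in a sample column: correlation is undefined (NA)")
    r <- NA_real_
  } else {
    r <- cor(x, y)
  }
  tibble::tibble(
    control = control, treatment = treatment,
    n_similar = n_sim, per_similar = 100 * n_sim / total_transcripts,
    r = r,
    n_different = n_diff, per_different = 100 * n_diff / total_transcripts,
    total_transcripts = total_transcripts
  )
}

#' Filter probes for the global heat map
#'
#' Keeps probes whose expression range across samples is at least
#' `min_range` (default 2 log2) and whose false-discovery-rate q-value is
#' strictly below `q_max` (default 0.01). The q-values are an input
#' supplied per probe, not computed here.
#'
#' @param expr Expression tibble.
#' @param qvalues Data frame `probe_id`, `q` covering every probe in
#'   `expr`; a probe without a q-value is an error.
#' @param min_range Minimum expression range, inclusive.
#' @param q_max FDR cutoff, exclusive (`q < q_max`).
#' @return Tibble `probe_id`, `expr_range`, `q` of retained probes.
#' @export
filter_heatmap_probes <- function(expr, qvalues, min_range = 2, q_max = 0.01) {
  expr <- .check_expression(expr)
  qvalues <- tibble::as_tibble(qvalues)
  if (!all(c("probe_id", "q") %in% names(qvalues))) {
    abort("`qvalues` must have columns `probe_id` and `q`")
  }
  vals <- as.matrix(expr[setdiff(names(expr), "probe_id")])
  rng <- apply(vals, 1, max) - apply(vals, 1, min)
  out <- dplyr::left_join(
    tibble::tibble(probe_id = expr$probe_id, expr_range = rng),
    qvalues, by = "probe_id")
  if (anyNA(out$q)) {
    miss <- out$probe_id[is.na(out$q)]
    abort(paste0("missing q-value for probe(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  dplyr::filter(out, .data$expr_range >= min_range, .data$q < q_max)
}

#' Collapse probe-level differential calls to genes
#'
#' A gene is taken as differentially expressed when any of its probes is
#' called differential. Returns the distinct genes behind non-similar
#' probes, optionally restricted by call direction.
#'
#' @param calls A [classify_fold_change()] result.
#' @param probe_gene_map Data frame `probe_id`, `gene`.
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return Character vector of gene symbols.
#' @export
differential_genes <- function(calls, probe_gene_map,
                               direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  map <- tibble::as_tibble(probe_gene_map)
  keep <- switch(direction,
                 any = calls$call != "similar",
                 up = calls$call == "up",
                 down = calls$call == "down")
  probes <- calls$probe_id[keep]
  genes <- map$gene[map$probe_id %in% probes]
  sort(unique(genes[!is.na(genes)]))
}
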