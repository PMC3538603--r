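# Comparative-CT (delta-delta-Ct) quantification. Ct tables travel in
# long format: one row per (condition, gene, replicate) with the observed
# threshold cycle.

.check_ct <- function(ct) {
  ct <- tibble::as_tibble(ct)
  required <- c("condition", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort("Ct values must be positive and finite")
  }
  ct
}

#' Normalise Ct values to a reference gene (delta-Ct)
#'
#' Replicate Ct values are arithmetically averaged per (condition, gene)
#' and then normalised against the reference gene measured in the same
#' condition: `delta_ct = mean Ct(gene) - mean Ct(reference)`, in cycles.
#' The relative expression level is `2^(-delta_ct)` (amplification
#' efficiency assumed to be exactly 2 per cycle).
#'
#' @param ct Long-format Ct table: columns `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param reference_gene Housekeeping gene used for normalisation
#'   (default `"Gapdh"`); must be measured in every condition.
#' @return Tibble `gene`, `condition`, `n_replicates`, `delta_ct`,
#'   `relative_level` (reference gene excluded).
#' @examples
#' ct <- tibble::tibble(
#'   condition = "Ctr", gene = rep(c("Gapdh", "Pla2g7"), each = 3),
#'   replicate = rep(1:3, 2), ct = c(20, 20, 20, 25, 25, 25))
#' delta_ct(ct) # delta_ct = 5, relative_level = 2^-5
#' @export
delta_ct <- function(ct, reference_gene = "Gapdh") {
  ct <- .check_ct(ct)
  means <- ct |>
    dplyr::group_by(.data$condition, .data$gene) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_ct = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(means, .data$gene == reference_gene)
  missing_ref <- setdiff(unique(means$condition), ref$condition)
  if (length(missing_ref) > 0) {
    abort(paste0("reference gene ", reference_gene,
                 " not measured in condition(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  if (any(means$n_replicates < 3)) {
    warn("some (condition, gene) pairs have fewer than 3 replicates; means use the available ones")
  }
  out <- means |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(dplyr::select(ref, "condition", ref_ct = "mean_ct"),
                     by = "condition") |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$ref_ct,
                  relative_level = 2^(-.data$delta_ct)) |>
    dplyr::select("gene", "condition", "n_replicates", "delta_ct",
                  "relative_level") |>
    dplyr::arrange(.data$gene, .data$condition)
  out
}

#' Log2 fold changes from delta-Ct values (delta-delta-Ct)
#'
#' For each gene and condition, `ddct = delta_ct(condition) -
#' delta_ct(control)` and the log2 fold change is `-ddct`: positive means
#' higher expression in the condition than in the control. The control
#' condition's fold change is identically zero.
#'
#' @param dct A [delta_ct()] result.
#' @param control Control condition label (default `"Ctr"`); every gene
#'   must have a delta-Ct in it.
#' @return Tibble `gene`, `condition`, `delta_ct`, `relative_level`,
#'   `log2_fc`.
#' @export
log2_fold_change <- function(dct, control = "Ctr") {
  dct <- tibble::as_tibble(dct)
  ctrl <- dplyr::filter(dct, .data$condition == control)
  missing_genes <- setdiff(unique(dct$gene), ctrl$gene)
  if (length(missing_genes) > 0) {
    abort(paste0("gene(s) missing in control condition ", control, ": ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  dct |>
    dplyr::left_join(dplyr::select(ctrl, "gene", ctrl_dct = "delta_ct"),
                     by = "gene") |>
    dplyr::mutate(log2_fc = -(.data$delta_ct - .data$ctrl_dct)) |>
    dplyr::select("gene", "condition", "delta_ct", "relative_level",
                  "log2_fc")
}

#' Select genes for qPCR validation
#'
#' Picks the probes whose expression changed by `min_abs_delta` or more
#' (default 1 log2, i.e. two-fold) in every listed comparison against the
#' control and whose FDR q-value is strictly below `q_max` (default 0.01),
#' then maps them to genes.
#'
#' @param callsets A list of [classify_fold_change()] results, one per
#'   treatment-vs-control comparison (e.g. C2 vs Ctr and C4 vs Ctr); a
#'   probe must pass the fold-change bound in all of them.
#' @param qvalues Data frame `probe_id`, `q` covering every probe.
#' @param probe_gene_map Optional data frame `probe_id`, `gene`.
#' @param min_abs_delta Minimum `|log2 fold change|`, inclusive.
#' @param q_max FDR cutoff, exclusive.
#' @return Tibble of selected probes (`probe_id`, `q`, one delta column
#'   per comparison, and `gene` if mapped).
#' @export
select_validation_genes <- function(callsets, qvalues, probe_gene_map = NULL,
                                    min_abs_delta = 1, q_max = 0.01) {
  if (inherits(callsets, "fold_change_calls")) callsets <- list(callsets)
  stopifnot(length(callsets) >= 1)
  qvalues <- tibble::as_tibble(qvalues)
  if (!all(c("probe_id", "q") %in% names(qvalues))) {
    abort("`qvalues` must have columns `probe_id` and `q`")
  }
  out <- tibble::tibble(probe_id = callsets[[1]]$probe_id)
  pass <- rep(TRUE, nrow(out))
  for (cs in callsets) {
    d <- cs$delta[match(out$probe_id, cs$probe_id)]
    col <- paste0("delta_", attr(cs, "treatment"), "_vs_", attr(cs, "control"))
    out[[col]] <- d
    pass <- pass & !is.na(d) & abs(d) >= min_abs_delta
  }
  out$q <- qvalues$q[match(out$probe_id, qvalues$probe_id)]
  if (anyNA(out$q[pass])) {
    miss <- out$probe_id[pass & is.na(out$q)]
    abort(paste0("missing q-value for probe(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  out <- out[pass & out$q < q_max, ]
  if (!is.null(probe_gene_map)) {
    out <- dplyr::left_join(out, tibble::as_tibble(probe_gene_map),
                            by = "probe_id")
  }
  out
}

#' Microarray-vs-qPCR concordance
#'
#' Ordinary least-squares fit of qPCR log2 fold changes on microarray
#' log2 fold changes over genes measured by both platforms, summarised by
#' the coefficient of determination `R^2 = 1 - SSres/SStot`. `R^2`
#' measures goodness of fit, not direction: perfectly anti-correlated
#' platforms would still score 1.
#'
#' @param data Data frame with one row per gene.
#' @param x,y Column names (strings) holding the microarray and qPCR log2
#'   fold changes.
#' @return Object of class `concordance` wrapping the [stats::lm()] fit;
#'   [glance()] gives a one-row tibble (`n`, `slope`, `intercept`,
#'   `r_squared`), [tidy()] the coefficient table.
#' @examples
#' d <- tibble::tibble(gene = c("a", "b", "c"),
#'                     array = c(0, 1, 2), qpcr = c(0, 1, 3))
#' glance(concordance(d, "array", "qpcr")) # R^2 = 27/28
#' @export
concordance <- function(data, x = "microarray_log2_fc", y = "qpcr_log2_fc") {
  data <- tibble::as_tibble(data)
  for (col in c(x, y)) {
    if (!col %in% names(data)) abort(paste0("column not found: ", col))
  }
  d <- data[stats::complete.cases(data[[x]], data[[y]]), ]
  if (nrow(d) < 3) abort("need at least 3 paired observations")
  if (stats::sd(d[[x]]) == 0) abort("zero variance in x: fit undefined")
  fit <- lm(d[[y]] ~ d[[x]])
  structure(list(fit = fit, n = nrow(d),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 x = x, y = y, data = d),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance> n = ", x$n,
      ", R^2 = ", format(x$r_squared, digits = 4),
      " (slope ", format(x$slope, digits = 4),
      ", intercept ", format(x$intercept, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance concordance
glance.concordance <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared)
}

#' @export
#' @method tidy concordance
tidy.concordance <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(sm[, "Estimate"]),
                 std_error = unname(sm[, "Std. Error"]),
                 statistic = unname(sm[, "t value"]),
                 p_value = unname(sm[, "Pr(>|t|)"]))
}
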