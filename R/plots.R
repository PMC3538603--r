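# ggplot2 views of the main result types. Each returns a ggplot object;
# nothing is drawn to a device.

#' Pairwise scatter plot of two samples
#'
#' One point per probe; the dashed lines mark the fold-change call
#' boundaries at `y = x +/- theta`, with points coloured by their call.
#'
#' @inheritParams classify_fold_change
#' @return A ggplot object.
#' @export
plot_scatter <- function(expr, control, treatment, theta = 1) {
  expr <- .check_expression(expr)
  calls <- classify_fold_change(expr, control, treatment, theta)
  d <- tibble::tibble(x = expr[[control]], y = expr[[treatment]],
                      call = calls$call)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_abline(intercept = c(theta, -theta), slope = 1,
                         linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "red3", similar = "grey40", down = "green4")) +
    ggplot2::labs(x = paste0(control, " (log2)"),
                  y = paste0(treatment, " (log2)"), colour = NULL)
}

#' Bar chart of enrichment results
#'
#' The `top_n` terms or sets by adjusted significance, drawn as
#' `-log10(q)` bars with the significant ones highlighted.
#'
#' @param results A [go_enrichment()] or [kegg_enrichment()] tibble.
#' @param top_n How many rows to show.
#' @param alpha FDR level for the reference line.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 10, alpha = 0.05) {
  results <- tibble::as_tibble(results)
  label_col <- if ("name" %in% names(results)) "name" else "set"
  d <- head(dplyr::arrange(results, .data$q, .data$p), top_n)
  d$label <- factor(d[[label_col]], levels = rev(d[[label_col]]))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$q), y = .data$label,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red3", `FALSE` = "grey60")) +
    ggplot2::labs(x = "-log10(q)", y = NULL, fill = paste0("q <= ", alpha))
}

#' Bar chart of GO term frequencies among study genes
#' @param freq A [go_term_frequency()] tibble.
#' @param top_n How many terms to show.
#' @return A ggplot object.
#' @export
plot_term_frequency <- function(freq, top_n = 12) {
  d <- head(tibble::as_tibble(freq), top_n)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_genes, y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "study genes annotated", y = NULL)
}

#' Microarray-vs-qPCR concordance plot
#'
#' The paired log2 fold changes with the least-squares line and the
#' coefficient of determination in the subtitle.
#'
#' @param fit A [concordance()] object.
#' @return A ggplot object.
#' @export
plot_concordance <- function(fit) {
  stopifnot(inherits(fit, "concordance"))
  d <- fit$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[fit$x]], y = .data[[fit$y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "red3") +
    ggplot2::labs(x = "microarray log2 fold change",
                  y = "qPCR log2 fold change",
                  subtitle = paste0("R² = ", format(fit$r_squared, digits = 4),
                                    " (n = ", fit$n, ")"))
}
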