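#' Configuration for an end-to-end pipeline run
#'
#' Collects input paths, condition labels, thresholds and the output
#' directory for [run_pipeline()]. Comparisons are always
#' treatment-vs-control with `control` as the designated control.
#'
#' @param expression_tsv Path to the log2 expression TSV.
#' @param probe_gene_tsv Path to the 2-column probe-to-gene TSV (read
#'   with [read_annotations_tsv()] column names remapped), or `NULL`.
#' @param obo Path to the OBO-subset ontology, or `NULL` to skip GO.
#' @param annotations_tsv Path to the gene-to-term TSV.
#' @param gmt Path to the gene-set GMT, or `NULL` to skip pathway
#'   enrichment.
#' @param qvalues_tsv Path to a per-probe q-value TSV (`probe_id`, `q`),
#'   or `NULL` to skip the heat-map filter and validation-gene selection.
#' @param ct_tsv Path to a long-format Ct TSV, or `NULL` to skip qPCR.
#' @param control Control sample label.
#' @param treatments Treatment labels; default every other sample.
#' @param theta Log2 fold-change call threshold.
#' @param min_range Background expression-range minimum, log2.
#' @param heatmap_min_range,heatmap_q_max Heat-map probe filter.
#' @param alpha Enrichment FDR level.
#' @param reference_gene qPCR reference gene.
#' @param total_transcripts Scatter-percentage denominator; `NULL` uses
#'   the probe count.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_tsv,
                            probe_gene_tsv = NULL,
                            obo = NULL,
                            annotations_tsv = NULL,
                            gmt = NULL,
                            qvalues_tsv = NULL,
                            ct_tsv = NULL,
                            control = "Ctr",
                            treatments = NULL,
                            theta = 1,
                            min_range = 1,
                            heatmap_min_range = 2,
                            heatmap_q_max = 0.01,
                            alpha = 0.05,
                            reference_gene = "Gapdh",
                            total_transcripts = NULL,
                            out_dir = tempfile("nscarray_run_"),
                            seed = 1L) {
  if (theta <= 0 || min_range < 0 || heatmap_min_range < 0 ||
      heatmap_q_max <= 0 || alpha <= 0) {
    abort("thresholds must be positive")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full downstream analysis pipeline
#'
#' Executes, in order: background selection; fold-change classification
#' of every treatment against the control; pairwise scatter summaries;
#' heat-map probe filtering and UPGMA clustering of the filtered probes
#' and of the samples; GO enrichment for the all-differential, up-only
#' and down-only study sets of each comparison; flat gene-set
#' enrichment; and, when a Ct table is supplied, comparative-CT
#' quantification with microarray concordance. Every result table is
#' written to `config$out_dir` along with a JSON run manifest (package
#' version, R version, configuration, seed) sufficient to reproduce the
#' run. A stage that fails validation aborts with a stage-named message;
#' tables already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with every in-memory result:
#'   `background`, `calls` (per treatment), `scatter`, `heatmap_probes`,
#'   `probe_tree`, `sample_tree`, `go` (per comparison and direction),
#'   `term_frequency`, `kegg`, `qpcr`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  res <- list()

  expr <- stage("read expression", read_expression_tsv(config$expression_tsv))
  map <- NULL
  if (!is.null(config$probe_gene_tsv)) {
    map <- stage("read probe-gene map", {
      m <- read_annotations_tsv(config$probe_gene_tsv)
      names(m) <- c("probe_id", "gene")
      m
    })
  }
  treatments <- config$treatments %||%
    setdiff(setdiff(names(expr), "probe_id"), config$control)
  total <- config$total_transcripts %||% nrow(expr)

  res$background <- stage("background selection",
    select_background(expr, config$min_range, map))
  readr::write_tsv(res$background, file.path(config$out_dir, "background.tsv"),
                   progress = FALSE)

  res$calls <- list()
  res$scatter <- list()
  for (tr in treatments) {
    cl <- stage(paste0("fold-change ", tr, " vs ", config$control),
                classify_fold_change(expr, config$control, tr, config$theta))
    res$calls[[tr]] <- cl
    readr::write_tsv(cl, file.path(config$out_dir,
                                   paste0("diffexpr_", tr, "_vs_",
                                          config$control, ".tsv")),
                     progress = FALSE)
    res$scatter[[tr]] <- stage(paste0("scatter ", tr),
      scatter_summary(expr, config$control, tr, config$theta, total))
  }
  scatter_tbl <- dplyr::bind_rows(res$scatter)
  readr::write_tsv(scatter_tbl, file.path(config$out_dir, "scatter_summary.tsv"),
                   progress = FALSE)
  res$scatter <- scatter_tbl

  qvals <- NULL
  if (!is.null(config$qvalues_tsv)) {
    qvals <- stage("read q-values",
                   readr::read_tsv(config$qvalues_tsv, show_col_types = FALSE,
                                   progress = FALSE))
    res$heatmap_probes <- stage("heat-map probe filter",
      filter_heatmap_probes(expr, qvals, config$heatmap_min_range,
                            config$heatmap_q_max))
    readr::write_tsv(res$heatmap_probes,
                     file.path(config$out_dir, "heatmap_probes.tsv"),
                     progress = FALSE)
    if (nrow(res$heatmap_probes) >= 2) {
      sub <- expr[expr$probe_id %in% res$heatmap_probes$probe_id, ]
      res$probe_tree <- stage("UPGMA probes", upgma_cluster(sub, axis = "probes"))
      write_linkage_tsv(res$probe_tree,
                        file.path(config$out_dir, "probe_linkage.tsv"))
      write_newick(res$probe_tree,
                   file.path(config$out_dir, "probe_tree.nwk"))
    }
  }
  res$sample_tree <- stage("UPGMA samples", upgma_cluster(expr, axis = "samples"))
  write_linkage_tsv(res$sample_tree,
                    file.path(config$out_dir, "sample_linkage.tsv"))
  write_newick(res$sample_tree, file.path(config$out_dir, "sample_tree.nwk"))

  if (!is.null(config$obo) && !is.null(config$annotations_tsv) &&
      !is.null(map)) {
    onto <- stage("read ontology", read_obo(config$obo))
    ann <- stage("read annotations", read_annotations_tsv(config$annotations_tsv))
    closed <- stage("annotation closure", propagate_annotations(onto, ann))
    background_genes <- sort(unique(res$background$gene[!is.na(res$background$gene)]))
    res$go <- list()
    res$term_frequency <- list()
    for (tr in treatments) {
      for (dir in c("any", "up", "down")) {
        study <- differential_genes(res$calls[[tr]], map, dir)
        study <- intersect(study, background_genes)
        key <- paste0(tr, "_", dir)
        if (length(study) == 0) next
        res$go[[key]] <- stage(paste0("GO enrichment ", key),
          go_enrichment(study, background_genes, onto, closed, config$alpha))
        write_enrichment_tsv(res$go[[key]],
                             file.path(config$out_dir,
                                       paste0("go_enrichment_", key, ".tsv")))
      }
      study_all <- intersect(differential_genes(res$calls[[tr]], map, "any"),
                             background_genes)
      if (length(study_all) > 0) {
        res$term_frequency[[tr]] <- stage(paste0("GO term frequency ", tr),
          go_term_frequency(study_all, onto, closed))
        readr::write_tsv(res$term_frequency[[tr]],
                         file.path(config$out_dir,
                                   paste0("go_term_frequency_", tr, ".tsv")),
                         progress = FALSE)
      }
    }
    if (!is.null(config$gmt)) {
      sets <- stage("read gene sets", read_gmt(config$gmt))
      res$kegg <- list()
      for (tr in treatments) {
        study <- intersect(differential_genes(res$calls[[tr]], map, "any"),
                           background_genes)
        if (length(study) == 0) next
        res$kegg[[tr]] <- stage(paste0("gene-set enrichment ", tr),
          kegg_enrichment(study, background_genes, sets, config$alpha))
        write_enrichment_tsv(res$kegg[[tr]],
                             file.path(config$out_dir,
                                       paste0("kegg_enrichment_", tr, ".tsv")))
      }
    }
  }

  if (!is.null(config$ct_tsv)) {
    ct <- stage("read Ct table", read_ct_tsv(config$ct_tsv))
    dct <- stage("delta-Ct", delta_ct(ct, config$reference_gene))
    res$qpcr <- stage("log2 fold change",
                      log2_fold_change(dct, config$control))
    readr::write_tsv(res$qpcr, file.path(config$out_dir, "qpcr_fold_changes.tsv"),
                     progress = FALSE)
    if (!is.null(map)) {
      # microarray gene-level log2 fold change for the last treatment in
      # the comparison matrix (the most perturbed condition), taking the
      # probe with the largest |delta| per gene
      tr <- treatments[length(treatments)]
      arr <- tibble::as_tibble(res$calls[[tr]]) |>
        dplyr::left_join(map, by = "probe_id") |>
        dplyr::filter(!is.na(.data$gene)) |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(microarray_log2_fc = .data$delta[which.max(abs(.data$delta))],
                         .groups = "drop")
      paired <- res$qpcr |>
        dplyr::filter(.data$condition == tr) |>
        dplyr::select("gene", qpcr_log2_fc = "log2_fc") |>
        dplyr::inner_join(arr, by = "gene")
      if (nrow(paired) >= 3) {
        res$concordance <- stage("concordance",
          concordance(paired, "microarray_log2_fc", "qpcr_log2_fc"))
        jsonlite::write_json(as.list(glance(res$concordance)),
                             file.path(config$out_dir, "concordance.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  manifest <- list(
    package = "nscarray",
    package_version = as.character(utils::packageVersion("nscarray")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Write every synthetic-study input to a directory
#'
#' Serialises a [simulate_study()] bundle into the standard plain-text
#' formats the pipeline consumes (expression TSV, probe-gene TSV, OBO
#' subset, annotation TSV, GMT, q-value TSV, Ct TSV) plus a truth JSON,
#' and returns a ready [pipeline_config()] pointing at them.
#'
#' @param study A [simulate_study()] bundle.
#' @param dir Output directory.
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A [pipeline_config()] for the written files.
#' @export
write_study <- function(study, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(study$expr, p("expression.tsv"))
  readr::write_tsv(study$probe_gene_map, p("probe_gene.tsv"),
                   col_names = FALSE, progress = FALSE)
  write_obo(study$ontology, p("ontology.obo"))
  write_annotations_tsv(study$annotations, p("annotations.tsv"))
  write_gmt(study$gene_sets, p("gene_sets.gmt"))
  readr::write_tsv(study$qvalues, p("qvalues.tsv"), progress = FALSE)
  write_ct_tsv(study$ct, p("ct.tsv"))
  truth <- list(
    seed = study$config$seed,
    planted_terms = study$planted_terms,
    planted_sets = study$planted_sets,
    panel_genes = study$panel_genes,
    n_de_c2 = sum(study$truth$de_c2),
    n_de_c4 = sum(study$truth$de_c4),
    note = paste("q-values are truth-linked placeholders (<0.01 for",
                 "planted differential probes), standing in for an",
                 "external per-probe FDR procedure"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  pipeline_config(
    expression_tsv = p("expression.tsv"),
    probe_gene_tsv = p("probe_gene.tsv"),
    obo = p("ontology.obo"),
    annotations_tsv = p("annotations.tsv"),
    gmt = p("gene_sets.gmt"),
    qvalues_tsv = p("qvalues.tsv"),
    ct_tsv = p("ct.tsv"),
    control = study$config$control,
    seed = study$config$seed,
    ...)
}
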