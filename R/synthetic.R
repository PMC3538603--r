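# Seeded synthetic study generator. Emulates the three-condition
# (Ctr/C2/C4) microarray design: array-scale probe set, a minority of
# planted differential probes with log2 shifts beyond the call threshold,
# C2 effects nested inside C4 effects, planted enrichment of differential
# genes in chosen ontology terms and gene sets, truth-linked per-probe
# q-values, and triplicate Ct tables consistent with the planted fold
# changes.

#' Configuration for a synthetic three-condition study
#'
#' Defaults emulate the motivating study design: 45,101 probes across
#' samples Ctr, C2 and C4; 312 differential probes in C4 vs Ctr of which
#' 38 are shared with C2 (nested perturbation — the C2 changes are a
#' strict subset of the C4 changes); 180/312 of the planted changes point
#' up; planted log2 shift 1.5; cell-level Gaussian noise 0.1 log2;
#' Ct-level noise 0.2 cycles. `n_varying` probes vary between C2 and C4
#' without crossing the differential threshold against Ctr, emulating the
#' expressed-but-unchanged transcripts that populate the enrichment
#' background.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the config.
#' @param n_probes Number of probes on the array.
#' @param samples Sample labels; first is taken as baseline unless
#'   `control` says otherwise.
#' @param control Control sample label.
#' @param probes_per_gene Probes mapping to each gene (1 keeps the truth
#'   table one-to-one; >1 exercises the any-probe collapsing rule).
#' @param baseline_mean,baseline_sd Per-probe baseline log2 intensity
#'   distribution.
#' @param n_de_c4,n_de_c2 Planted differential probe counts in C4 vs Ctr
#'   and C2 vs Ctr; the C2 set is a subset of the C4 set.
#' @param prop_up Fraction of planted changes that are upregulations.
#' @param effect_size Minimum planted |log2 fold change|.
#' @param effect_size_spread Per-gene planted magnitudes are drawn
#'   uniformly from `[effect_size, effect_size + effect_size_spread]`,
#'   giving the spread of strong and moderate changes a real perturbation
#'   produces (and populating the range-2 heat-map filter).
#' @param noise_sd Per-cell Gaussian noise, log2 units.
#' @param n_varying Probes with anti-symmetric sub-threshold C2/C4
#'   offsets (background filler).
#' @param planted_terms Ontology term accessions whose annotated genes
#'   seed the differential set, or `NULL` to let [simulate_study()] pick
#'   one.
#' @param rho Fraction of differential genes drawn from the planted
#'   terms' annotated genes.
#' @param ct_noise_sd Gaussian noise on synthetic Ct values, cycles.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_probes = 45101L,
                              samples = c("Ctr", "C2", "C4"),
                              control = "Ctr",
                              probes_per_gene = 1L,
                              baseline_mean = 7,
                              baseline_sd = 2,
                              n_de_c4 = 312L,
                              n_de_c2 = 38L,
                              prop_up = 180 / 312,
                              effect_size = 1.5,
                              effect_size_spread = 1,
                              noise_sd = 0.1,
                              n_varying = 4000L,
                              planted_terms = NULL,
                              rho = 0.4,
                              ct_noise_sd = 0.2) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              samples = samples, control = control,
              probes_per_gene = as.integer(probes_per_gene),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              n_de_c4 = as.integer(n_de_c4), n_de_c2 = as.integer(n_de_c2),
              prop_up = prop_up, effect_size = effect_size,
              effect_size_spread = effect_size_spread,
              noise_sd = noise_sd, n_varying = as.integer(n_varying),
              planted_terms = planted_terms, rho = rho,
              ct_noise_sd = ct_noise_sd)
  if (!cfg$control %in% cfg$samples) abort("`control` must be one of `samples`")
  if (cfg$n_de_c2 > cfg$n_de_c4) abort("`n_de_c2` must be <= `n_de_c4` (nested design)")
  if (cfg$n_de_c4 + cfg$n_varying > cfg$n_probes) {
    abort("planted + varying probes exceed `n_probes`")
  }
  if (cfg$effect_size <= 0) abort("`effect_size` must be positive")
  if (cfg$effect_size_spread < 0) abort("`effect_size_spread` must be >= 0")
  if (cfg$noise_sd < 0 || cfg$ct_noise_sd < 0) abort("noise sds must be >= 0")
  if (cfg$rho < 0 || cfg$rho > 1) abort("`rho` must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Generate a random acyclic ontology
#'
#' Terms are created in order and each non-root term draws 1 to
#' `max_parents` parents among earlier terms of the same namespace, so
#' the graph is acyclic by construction with one root per namespace.
#'
#' @param n_terms Total number of terms (split evenly over namespaces).
#' @param max_parents Maximum is_a parents per term.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param namespaces Namespace names, one root each.
#' @return An [ontology()].
#' @export
generate_ontology <- function(n_terms, max_parents = 3, seed = NULL,
                              namespaces = "biological_process") {
  if (!is.null(seed)) set.seed(seed)
  if (n_terms < length(namespaces)) {
    abort("need at least one term per namespace")
  }
  per_ns <- diff(floor(seq(0, n_terms, length.out = length(namespaces) + 1)))
  rows <- list()
  counter <- 0L
  for (h in seq_along(namespaces)) {
    ids <- sprintf("GO:%07d", counter + seq_len(per_ns[h]))
    counter <- counter + per_ns[h]
    parents <- vector("list", per_ns[h])
    parents[[1]] <- character()
    if (per_ns[h] > 1) {
      for (i in 2:per_ns[h]) {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        parents[[i]] <- sort(sample(ids[seq_len(i - 1L)], k))
      }
    }
    rows[[h]] <- tibble::tibble(
      term_id = ids,
      name = paste0("synthetic term ", ids),
      namespace = namespaces[h],
      parents = parents)
  }
  ontology(dplyr::bind_rows(rows))
}

#' Generate random direct gene annotations
#'
#' Assigns each gene between `min_terms` and `max_terms` direct terms
#' drawn uniformly from the non-root terms of the ontology.
#'
#' @param onto An [ontology()].
#' @param genes Character vector of gene symbols.
#' @param min_terms,max_terms Direct terms per gene.
#' @param seed Optional seed.
#' @return Tibble `gene`, `term_id` (direct, not closed).
#' @export
generate_annotations <- function(onto, genes, min_terms = 1, max_terms = 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(onto$terms$term_id, onto$roots)
  if (length(pool) == 0) pool <- onto$terms$term_id
  n_terms <- sample(seq(min_terms, max_terms), length(genes), replace = TRUE)
  tibble::tibble(
    gene = rep(genes, n_terms),
    term_id = unlist(lapply(n_terms, function(k) {
      sample(pool, min(k, length(pool)))
    }), use.names = FALSE))
}

#' Generate flat gene sets (synthetic pathways)
#'
#' Random sets of genes, optionally with planted sets whose members are
#' drawn preferentially from a supplied gene pool (e.g. the planted
#' differential genes) so that set enrichment is recoverable.
#'
#' @param genes Universe of gene symbols.
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param planted_from Gene pool for planted sets, or `NULL`.
#' @param n_planted How many of the sets are planted.
#' @param planted_frac Fraction of a planted set drawn from
#'   `planted_from`.
#' @param seed Optional seed.
#' @return Tibble `set`, `description`, `gene`; planted sets are named
#'   `plantedNN` and flagged in `description`.
#' @export
generate_gene_sets <- function(genes, n_sets = 20, set_size = 40,
                               planted_from = NULL, n_planted = 0,
                               planted_frac = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_planted > 0 && is.null(planted_from)) {
    abort("`planted_from` required when `n_planted` > 0")
  }
  out <- list()
  for (s in seq_len(n_sets)) {
    planted <- s <= n_planted
    if (planted) {
      k <- round(planted_frac * set_size)
      k <- min(k, length(planted_from))
      members <- c(sample(planted_from, k),
                   sample(setdiff(genes, planted_from), set_size - k))
      nm <- sprintf("planted%02d", s)
      desc <- "planted enriched set"
    } else {
      members <- sample(genes, set_size)
      nm <- sprintf("pathway%02d", s)
      desc <- "random set"
    }
    out[[s]] <- tibble::tibble(set = nm, description = desc, gene = members)
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic expression matrix with planted differentials
#'
#' Per probe, a baseline log2 intensity is drawn from
#' `Normal(baseline_mean, baseline_sd)` and shared across samples;
#' planted differential probes get a signed shift of at least
#' `effect_size` log2 units in C4 (a nested subset also in C2, same
#' shift); `n_varying` filler probes get
#' anti-symmetric sub-threshold offsets in C2/C4 (so they enter the
#' range-based background without being differential against Ctr);
#' independent `Normal(0, noise_sd)` noise is added per cell. When
#' `config$planted_terms` is set (with annotations supplied), a fraction
#' `rho` of the differential genes is drawn from the genes annotated to
#' those terms, planting recoverable term enrichment. Emitted q-values
#' are truth-linked placeholders: below 0.01 for planted differential
#' probes and at or above 0.01 otherwise.
#'
#' @param config A [simulation_config()].
#' @param annotations Optional closed or direct annotations, required
#'   when `config$planted_terms` is set.
#' @param onto Optional [ontology()], used to close `annotations` if
#'   needed.
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return List: `expr` (expression tibble), `probe_gene_map`, `truth`
#'   (per-probe tibble: gene, planted calls and true log2 fold changes
#'   per non-control sample), `qvalues`.
#' @export
generate_expression <- function(config, annotations = NULL, onto = NULL,
                                seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_probes
  probes <- sprintf("P%06d", seq_len(n))
  n_genes <- ceiling(n / config$probes_per_gene)
  genes <- sprintf("G%06d", seq_len(n_genes))
  map <- tibble::tibble(probe_id = probes,
                        gene = rep(genes, each = config$probes_per_gene)[seq_len(n)])

  treatments <- setdiff(config$samples, config$control)

  # pick differential GENES (so multi-probe mode stays coherent), a
  # fraction rho of them from the planted terms' annotated genes
  n_de_genes <- config$n_de_c4
  de_genes <- character(0)
  if (!is.null(config$planted_terms) && length(config$planted_terms) > 0) {
    if (is.null(annotations)) {
      abort("`annotations` required when `config$planted_terms` is set")
    }
    if (!is_closed(annotations)) {
      if (is.null(onto)) abort("`onto` required to close `annotations`")
      annotations <- propagate_annotations(onto, annotations)
    }
    pool <- unique(annotations$gene[annotations$term_id %in% config$planted_terms])
    pool <- intersect(pool, genes)
    n_from_term <- round(config$rho * n_de_genes)
    if (n_from_term > length(pool)) {
      abort(paste0("planted terms annotate only ", length(pool),
                   " genes; cannot draw ", n_from_term, " differential genes"))
    }
    de_genes <- sample(pool, n_from_term)
  }
  de_genes <- c(de_genes,
                sample(setdiff(genes, de_genes),
                       n_de_genes - length(de_genes)))
  de_probes_c4 <- map$probe_id[map$gene %in% de_genes]
  # in multi-probe mode all probes of a differential gene shift together
  de_c2_genes <- de_genes[seq_len(config$n_de_c2)]
  de_probes_c2 <- map$probe_id[map$gene %in% de_c2_genes]

  direction <- setNames(rep(0, n), probes)
  n_up <- round(config$prop_up * length(de_genes))
  up_genes <- de_genes[seq_len(n_up)]
  direction[map$gene %in% up_genes] <- 1
  direction[map$gene %in% setdiff(de_genes, up_genes)] <- -1

  # per-gene planted magnitude, shared by all probes of the gene and by
  # the C2 and C4 conditions (nested perturbation, same shift)
  gene_mag <- setNames(runif(length(de_genes), config$effect_size,
                             config$effect_size + config$effect_size_spread),
                       de_genes)
  magnitude <- setNames(rep(0, n), probes)
  in_de <- map$gene %in% de_genes
  magnitude[in_de] <- gene_mag[map$gene[in_de]]

  # anti-symmetric sub-threshold C2/C4 offsets for background filler
  free <- setdiff(probes, de_probes_c4)
  varying <- sample(free, config$n_varying)
  w <- runif(config$n_varying, 1.0, 1.2)
  vsign <- sample(c(-1, 1), config$n_varying, replace = TRUE)
  off_c2 <- setNames(rep(0, n), probes)
  off_c4 <- setNames(rep(0, n), probes)
  off_c2[varying] <- -vsign * w / 2
  off_c4[varying] <- vsign * w / 2

  shift_c4 <- ifelse(probes %in% de_probes_c4, direction * magnitude, 0) + off_c4
  shift_c2 <- ifelse(probes %in% de_probes_c2, direction * magnitude, 0) + off_c2

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  expr <- tibble::tibble(probe_id = probes)
  for (s in config$samples) {
    shift <- if (s == config$control) 0 else if (s == "C2") shift_c2
             else if (s == "C4") shift_c4 else 0
    expr[[s]] <- unname(baseline + shift + rnorm(n, 0, config$noise_sd))
  }

  truth <- tibble::tibble(
    probe_id = probes,
    gene = map$gene,
    de_c2 = probes %in% de_probes_c2,
    de_c4 = probes %in% de_probes_c4,
    direction = unname(direction),
    # the full planted shift, including the sub-threshold offsets of the
    # varying filler probes, so zero-noise deltas reproduce it exactly
    true_lfc_C2 = unname(shift_c2),
    true_lfc_C4 = unname(shift_c4))

  qvalues <- tibble::tibble(
    probe_id = probes,
    q = ifelse(truth$de_c4,
               runif(n, 1e-6, 0.0099),
               runif(n, 0.0101, 1)))

  list(expr = expr, probe_gene_map = map, truth = truth, qvalues = qvalues)
}

#' Generate a synthetic triplicate Ct table from planted fold changes
#'
#' The reference gene amplifies at a Ct of about 20 cycles; each panel
#' gene gets a fixed baseline delta-Ct (uniform over 2-8 cycles) and its
#' Ct in a condition is shifted down by the planted log2 fold change
#' (higher expression, earlier amplification). Gaussian technical noise
#' of `ct_noise_sd` cycles is added per well; at zero noise the
#' comparative-CT pipeline recovers the planted fold changes exactly.
#'
#' @param truth A truth tibble from [generate_expression()] (per-probe
#'   `gene` and `true_lfc_*` columns), or any tibble with `gene` plus
#'   `true_lfc_<sample>` columns.
#' @param genes Panel of gene symbols to assay; must appear in `truth`.
#' @param conditions Condition labels; those without a `true_lfc_`
#'   column (the control) get fold change 0.
#' @param ct_noise_sd Noise in cycles.
#' @param n_replicates Wells per (condition, gene).
#' @param reference_gene Reference gene symbol added to every condition.
#' @param seed Optional seed.
#' @return Long-format Ct tibble (`condition`, `gene`, `replicate`,
#'   `ct`).
#' @export
generate_ct_table <- function(truth, genes, conditions = c("Ctr", "C2", "C4"),
                              ct_noise_sd = 0.2, n_replicates = 3,
                              reference_gene = "Gapdh", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- tibble::as_tibble(truth)
  missing_genes <- setdiff(genes, truth$gene)
  if (length(missing_genes) > 0) {
    abort(paste0("panel gene(s) absent from truth: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  base_dct <- setNames(runif(length(genes), 2, 8), genes)
  lfc <- function(gene, cond) {
    col <- paste0("true_lfc_", cond)
    if (!col %in% names(truth)) return(0)
    # gene-level truth: any probe of the gene carries the planted shift
    v <- truth[[col]][truth$gene == gene]
    v[which.max(abs(v))]
  }
  rows <- list()
  for (cond in conditions) {
    for (g in c(reference_gene, genes)) {
      mu <- if (g == reference_gene) 20 else 20 + base_dct[[g]] - lfc(g, cond)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, gene = g,
        replicate = seq_len(n_replicates),
        ct = mu + rnorm(n_replicates, 0, ct_noise_sd))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete synthetic study
#'
#' Generates, deterministically from `config$seed`, every input the
#' pipeline consumes: an ontology, direct gene annotations, flat gene
#' sets with two planted pathways, an expression matrix with planted
#' differential probes (seeded from one planted mid-sized ontology term
#' when `config$planted_terms` is `NULL`), truth-linked q-values, and a
#' triplicate Ct table for a 12-gene validation panel.
#'
#' @param config A [simulation_config()].
#' @param n_terms,max_parents Ontology size parameters.
#' @param namespaces Ontology namespaces.
#' @return List: `config`, `ontology`, `annotations` (direct),
#'   `gene_sets`, `expr`, `probe_gene_map`, `truth`, `qvalues`, `ct`,
#'   `panel_genes`, `planted_terms`, `planted_sets`.
#' @export
simulate_study <- function(config = simulation_config(),
                           n_terms = 300, max_parents = 3,
                           namespaces = c("biological_process",
                                          "molecular_function",
                                          "cellular_component")) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  onto <- generate_ontology(n_terms, max_parents, seed = NULL,
                            namespaces = namespaces)
  n_genes <- ceiling(config$n_probes / config$probes_per_gene)
  genes <- sprintf("G%06d", seq_len(n_genes))
  ann <- generate_annotations(onto, genes, seed = NULL)
  closed <- propagate_annotations(onto, ann)

  planted_terms <- config$planted_terms
  if (is.null(planted_terms)) {
    # a mid-sized biological_process term: big enough to supply the
    # differential genes, small enough to be specific
    ns <- setNames(onto$terms$namespace, onto$terms$term_id)
    sizes <- closed |>
      dplyr::filter(ns[.data$term_id] == "biological_process",
                    .data$term_id != onto$roots[["biological_process"]]) |>
      dplyr::count(.data$term_id)
    need <- round(config$rho * config$n_de_c4)
    ok <- sizes[sizes$n >= max(2 * need, need + 10), ]
    if (nrow(ok) == 0) abort("no ontology term large enough to plant enrichment in")
    planted_terms <- ok$term_id[which.min(ok$n)]
    config$planted_terms <- planted_terms
  }

  gen <- generate_expression(config, annotations = closed, seed = NULL)
  de_genes <- unique(gen$truth$gene[gen$truth$de_c4])
  sets <- generate_gene_sets(genes, n_sets = 20, set_size = 40,
                             planted_from = de_genes, n_planted = 2,
                             planted_frac = 0.4, seed = NULL)
  panel <- c(sample(de_genes, 8),
             sample(setdiff(genes, de_genes), 4))
  ct <- generate_ct_table(gen$truth, panel,
                          conditions = config$samples,
                          ct_noise_sd = config$ct_noise_sd,
                          reference_gene = "Gapdh", seed = NULL)
  list(config = config, ontology = onto, annotations = ann,
       gene_sets = sets, expr = gen$expr,
       probe_gene_map = gen$probe_gene_map, truth = gen$truth,
       qvalues = gen$qvalues, ct = ct, panel_genes = panel,
       planted_terms = planted_terms,
       planted_sets = unique(sets$set[sets$description == "planted enriched set"]))
}
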