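test_that("hypergeometric upper tail matches enumeration and phyper", {
  expect_equal(hypergeom_upper_tail(10, 4, 5, 0), 1)   # P(X >= 0)
  expect_equal(hypergeom_upper_tail(10, 10, 5, 3), 1)  # K = N: X = n surely
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3), 11 / 42, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3),
               enum_hypergeom_tail(10, 4, 5, 3), tolerance = 1e-12)
  # spot checks against the independent stats route
  set.seed(8)
  for (rep in 1:50) {
    N <- sample(5:5000, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample.int(min(K, n), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(10, 11, 5, 3), "K <= N")
  expect_error(hypergeom_upper_tail(10, 4, 5, 5), "min\\(K, n\\)")
})

test_that("p never increases as k grows with other counts fixed", {
  for (N in c(20, 200)) {
    K <- N %/% 4; n <- N %/% 5
    p <- vapply(0:min(K, n), function(k) hypergeom_upper_tail(N, K, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("Benjamini-Hochberg matches its definition and p.adjust", {
  one <- benjamini_hochberg(0.03)
  expect_equal(one$q, 0.03)  # m = 1

  bh <- benjamini_hochberg(c(0.01, 0.04, 0.03, 0.02), alpha = 0.05)
  expect_equal(bh$q, rep(0.04, 4))
  expect_true(all(bh$significant))

  ones <- benjamini_hochberg(rep(1, 7))
  expect_equal(ones$q, rep(1, 7))
  expect_false(any(ones$significant))

  set.seed(13)
  for (rep in 1:25) {
    m <- sample(1:300, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- benjamini_hochberg(p)$q
    expect_identical(q, brute_bh(p))
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GO enrichment counts, ranks and flags a planted term", {
  # background of 200 genes; one term annotates 20 of them; the study
  # set of 20 contains 10 term genes
  onto <- ontology(tibble::tibble(
    term_id = c("R", "T", "U"), name = c("root", "planted", "other"),
    namespace = "biological_process",
    parents = list(character(), "R", "R")))
  genes <- sprintf("g%03d", 1:200)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = genes, term_id = "R"),
    tibble::tibble(gene = genes[1:20], term_id = "T"),
    tibble::tibble(gene = genes[181:200], term_id = "U"))
  study <- c(genes[1:10], genes[21:30])
  res <- go_enrichment(study, genes, onto, ann)
  top <- res[1, ]
  expect_equal(top$term_id, "T")
  expect_equal(c(top$N, top$K, top$n, top$k), c(200, 20, 20, 10))
  expect_equal(top$p, stats::phyper(9, 20, 180, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(top$significant)
  expect_setequal(top$genes[[1]], genes[1:10])
  # the root annotates everyone: k = n, K = N, p = 1
  root_row <- res[res$term_id == "R", ]
  expect_equal(root_row$p, 1)
})

test_that("enrichment is identical on pre-closed and lazily closed annotations", {
  set.seed(19)
  parents <- random_parent_list(30)
  onto <- parent_list_to_ontology(parents)
  genes <- paste0("g", 1:100)
  direct <- tibble::tibble(gene = sample(genes, 150, replace = TRUE),
                           term_id = sample(names(parents), 150, replace = TRUE))
  study <- sample(genes, 25)
  lazy <- go_enrichment(study, genes, onto, direct)
  pre <- go_enrichment(study, genes, onto, propagate_annotations(onto, direct))
  expect_equal(lazy, pre)
})

test_that("study genes outside the background are dropped with a warning", {
  onto <- chain_ontology()
  genes <- paste0("g", 1:50)
  ann <- tibble::tibble(gene = genes, term_id = "B")
  expect_warning(res <- go_enrichment(c(genes[1:5], "alien"), genes, onto, ann),
                 "alien")
  expect_equal(res$n[1], 5)
  expect_error(go_enrichment(character(), genes, onto, ann), "empty")
  expect_error(suppressWarnings(go_enrichment("alien", genes, onto, ann)),
               "no study genes")
})

test_that("flat-set enrichment mirrors the GO machinery without propagation", {
  genes <- sprintf("g%03d", 1:100)
  sets <- dplyr::bind_rows(
    tibble::tibble(set = "hit", description = "d", gene = genes[1:10]),
    tibble::tibble(set = "miss", description = "d", gene = genes[51:60]),
    tibble::tibble(set = "outside", description = "d", gene = "alien"))
  study <- genes[1:10]
  res <- kegg_enrichment(study, genes, sets)
  expect_equal(res$set[1], "hit")
  expect_equal(res$k[res$set == "hit"], 10)
  expect_setequal(res$genes[[which(res$set == "hit")]], study)
  expect_false("outside" %in% res$set)  # K = 0 after background intersection
  # zero overlap everywhere: all p = 1, nothing significant
  res2 <- kegg_enrichment(genes[90:99], genes,
                          dplyr::filter(sets, set == "miss"))
  expect_equal(res2$p, 1)
  expect_false(any(res2$significant))
})

test_that("BH correction is applied within each namespace separately", {
  onto <- ontology(tibble::tibble(
    term_id = c("bpR", "bpT", "mfR", "mfT"),
    name = c("bp root", "bp term", "mf root", "mf term"),
    namespace = rep(c("biological_process", "molecular_function"), each = 2),
    parents = list(character(), "bpR", character(), "mfR")))
  genes <- paste0("g", 1:40)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = genes[1:10], term_id = "bpT"),
    tibble::tibble(gene = genes[1:10], term_id = "mfT"),
    tibble::tibble(gene = genes, term_id = "bpR"),
    tibble::tibble(gene = genes, term_id = "mfR"))
  res <- go_enrichment(genes[1:10], genes, onto, ann)
  for (ns in c("biological_process", "molecular_function")) {
    sub <- res[res$namespace == ns, ]
    expect_identical(sub$q, benjamini_hochberg(sub$p)$q)
  }
})

test_that("term frequencies count closed annotations and drop the root", {
  onto <- chain_ontology()
  ann <- tibble::tibble(gene = c("g1", "g2"), term_id = c("B", "A"))
  freq <- go_term_frequency(c("g1", "g2"), onto, ann)
  expect_false("R" %in% freq$term_id)
  expect_equal(freq$n_genes[freq$term_id == "A"], 2)  # g1 via closure
  expect_equal(freq$n_genes[freq$term_id == "B"], 1)
  # genes on disjoint branches each count once for their own branch
  dia <- diamond_ontology()
  ann2 <- tibble::tibble(gene = c("x", "y"), term_id = c("B", "C"))
  freq2 <- go_term_frequency(c("x", "y"), dia, ann2)
  expect_equal(freq2$n_genes[freq2$term_id %in% c("B", "C")], c(1, 1))
  expect_error(go_term_frequency("x", dia, ann2, namespace = "nope"), "nope")
})
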