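test_that("ancestors returns the reflexive transitive closure", {
  expect_setequal(ontology_ancestors(chain_ontology(), "R"), "R")
  expect_setequal(ontology_ancestors(chain_ontology(), "B"), c("B", "A", "R"))
  expect_setequal(ontology_ancestors(diamond_ontology(), "D"),
                  c("D", "B", "C", "R"))
  expect_error(ontology_ancestors(chain_ontology(), "nope"), "nope")
})

test_that("construction rejects cycles, dangling parents and double roots", {
  cyclic <- tibble::tibble(
    term_id = c("A", "B"), name = c("a", "b"),
    namespace = "biological_process", parents = list("B", "A"))
  expect_error(ontology(cyclic), "cycle")
  dangling <- tibble::tibble(
    term_id = "A", name = "a", namespace = "biological_process",
    parents = list("ghost"))
  expect_error(ontology(dangling), "ghost")
  two_roots <- tibble::tibble(
    term_id = c("A", "B"), name = c("a", "b"),
    namespace = "biological_process",
    parents = list(character(), character()))
  expect_error(ontology(two_roots), "root")
})

test_that("back-propagation closes annotations to the root", {
  onto <- chain_ontology()
  closed <- propagate_annotations(onto, tibble::tibble(gene = "g1", term_id = "B"))
  expect_setequal(closed$term_id, c("B", "A", "R"))
  expect_true(is_closed(closed))

  # gene annotated only to the root
  root_only <- propagate_annotations(onto, tibble::tibble(gene = "g", term_id = "R"))
  expect_equal(root_only$term_id, "R")

  # empty map closes to an empty map
  empty <- propagate_annotations(onto, tibble::tibble(gene = character(),
                                                      term_id = character()))
  expect_equal(nrow(empty), 0)
  expect_true(is_closed(empty))

  # annotation to an unknown term is a validation error naming the pair
  expect_error(
    propagate_annotations(onto, tibble::tibble(gene = "g", term_id = "Z")),
    "g -> Z")
})

test_that("closure is idempotent, monotone and root-total", {
  set.seed(11)
  for (rep in 1:10) {
    parents <- random_parent_list(sample(5:40, 1))
    onto <- parent_list_to_ontology(parents)
    genes <- paste0("g", 1:15)
    direct <- tibble::tibble(
      gene = sample(genes, 30, replace = TRUE),
      term_id = sample(names(parents), 30, replace = TRUE))
    closed <- propagate_annotations(onto, direct)
    again <- propagate_annotations(onto, closed)
    expect_equal(again, closed)
    per_gene_direct <- table(unique(direct)$gene)
    per_gene_closed <- table(unique(closed)$gene)
    expect_true(all(per_gene_closed[names(per_gene_direct)] >= per_gene_direct))
    # every annotated gene reaches the namespace root
    root <- onto$roots[["biological_process"]]
    expect_true(all(vapply(split(closed$term_id, closed$gene),
                           function(t) root %in% t, logical(1))))
    # direct annotations are a subset of the closure
    expect_true(all(paste(direct$gene, direct$term_id) %in%
                      paste(closed$gene, closed$term_id)))
  }
})

test_that("closure matches brute-force reachability on random DAGs", {
  set.seed(42)
  for (rep in 1:25) {
    parents <- random_parent_list(sample(2:50, 1))
    onto <- parent_list_to_ontology(parents)
    for (t in sample(names(parents), min(5, length(parents)))) {
      expect_setequal(ontology_ancestors(onto, t), brute_ancestors(parents, t))
    }
  }
})

test_that("OBO subset reader honours id/name/namespace/is_a and drops obsoletes", {
  f <- withr::local_tempfile(lines = c(
    "format-version: 1.2",
    "date: ignored",
    "",
    "[Term]",
    "id: GO:1",
    "name: root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:2",
    "name: child",
    "namespace: biological_process",
    "def: some ignored definition",
    "is_a: GO:1 ! root",
    "relationship: part_of GO:1",
    "",
    "[Term]",
    "id: GO:3",
    "name: gone",
    "namespace: biological_process",
    "is_a: GO:1",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of"))
  onto <- read_obo(f)
  expect_setequal(onto$terms$term_id, c("GO:1", "GO:2"))
  expect_equal(onto$parents[["GO:2"]], "GO:1")   # "! root" comment stripped
  expect_equal(onto$roots[["biological_process"]], "GO:1")
})

test_that("annotation TSV reader allows comments and collapses duplicates", {
  f <- withr::local_tempfile(lines = c(
    "# a comment",
    "g1\tGO:1",
    "g1\tGO:1",
    "g2\tGO:2"))
  ann <- read_annotations_tsv(f)
  expect_equal(nrow(ann), 2)
  bad <- withr::local_tempfile(lines = c("g1\tGO:1", "g2"))
  expect_error(read_annotations_tsv(bad), "line 2")
})

test_that("ontology round-trips through the OBO writer", {
  set.seed(3)
  onto <- generate_ontology(30, 3, namespaces = c("biological_process",
                                                  "molecular_function"))
  f <- withr::local_tempfile()
  write_obo(onto, f)
  back <- read_obo(f)
  expect_equal(back$terms$term_id, onto$terms$term_id)
  expect_equal(back$terms$namespace, onto$terms$namespace)
  expect_equal(lapply(back$terms$parents, sort),
               lapply(onto$terms$parents, sort))
})
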