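# Independent brute-force oracles used to cross-check the package's
# implementations. Each deliberately takes the most literal route.

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n)
# draws: genes 1..K are annotated; count draws with >= k annotated
enum_hypergeom_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# definition-based BH: q_(i) = min over j >= i of p_(j) * m / j, capped
# at 1, mapped back to input order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  q_sorted <- vapply(seq_len(m), function(i) min(1, min(raw[i:m])), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# reachability closure by repeated edge expansion until fixpoint
brute_ancestors <- function(parents, start) {
  out <- start
  repeat {
    grown <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(grown) == length(out)) return(sort(out))
    out <- grown
  }
}

# naive O(n^3) average linkage: cluster distances recomputed from the
# original leaf distance matrix at every step; same tie-break rule as
# the implementation (lexicographically smallest sorted label pair)
naive_upgma <- function(D, labels) {
  clusters <- as.list(seq_along(labels))
  clabs <- labels
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(D[clusters[[a]], clusters[[b]]])
        pair <- sort(c(clabs[a], clabs[b]))
        if (is.null(best) || dd < best$d ||
            (dd == best$d && (pair[1] < best$pair[1] ||
                              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(a = a, b = b, d = dd, pair = pair)
        }
      }
    }
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    merges[[length(merges) + 1L]] <- sort(labels[merged])
    heights <- c(heights, best$d)
    clusters[[best$a]] <- merged
    clabs[best$a] <- min(clabs[best$a], clabs[best$b])
    clusters[[best$b]] <- NULL
    clabs <- clabs[-best$b]
  }
  list(merges = merges, heights = heights)
}

# leaf-label sets of each merge of an hclust-style tree, for comparing
# merge order against the naive oracle
merge_leaf_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  leaves <- function(k) if (k < 0) tree$labels[-k] else sets[[k]]
  for (i in seq_len(nrow(tree$merge))) {
    sets[[i]] <- sort(c(leaves(tree$merge[i, 1]), leaves(tree$merge[i, 2])))
  }
  sets
}

# tiny fixed ontologies used across test files
chain_ontology <- function() {
  ontology(tibble::tibble(
    term_id = c("R", "A", "B"),
    name = c("root", "mid", "leaf"),
    namespace = "biological_process",
    parents = list(character(), "R", "A")))
}

diamond_ontology <- function() {
  ontology(tibble::tibble(
    term_id = c("R", "B", "C", "D"),
    name = paste("term", c("R", "B", "C", "D")),
    namespace = "biological_process",
    parents = list(character(), "R", "R", c("B", "C"))))
}

# random DAG expressed as a parent list (acyclic by construction:
# edges only point to earlier terms), for the reachability oracle
random_parent_list <- function(n_terms, max_parents = 3) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- setNames(vector("list", n_terms), ids)
  parents[[1]] <- character()
  if (n_terms > 1) {
    for (i in 2:n_terms) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[i]] <- sample(ids[seq_len(i - 1L)], k)
    }
  }
  parents
}

parent_list_to_ontology <- function(parents) {
  ontology(tibble::tibble(
    term_id = names(parents),
    name = names(parents),
    namespace = "biological_process",
    parents = unname(parents)))
}
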