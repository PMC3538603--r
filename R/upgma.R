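#' UPGMA clustering on one-minus-correlation distances
#'
#' Agglomerative hierarchical clustering of expression profiles under the
#' unweighted pair-group method with arithmetic mean (UPGMA, average
#' linkage): the distance between two profiles is `1 - Pearson r`, the
#' distance between two clusters is the arithmetic mean of all leaf-pair
#' distances, and at each step the closest pair of clusters is merged.
#' Merge heights are non-decreasing (the UPGMA ultrametric property).
#'
#' Ties (two pairs at the same minimal distance) are broken by the
#' lexicographically smallest pair of cluster labels, where a merged
#' cluster is labelled by its lexicographically smallest leaf, so the
#' output is deterministic. A zero-variance profile makes the correlation
#' undefined and aborts with an error naming the profile.
#'
#' @param x Either a numeric matrix with profiles in rows (rownames are
#'   the leaf labels) or an expression tibble (`probe_id` + sample
#'   columns).
#' @param axis For a tibble: `"samples"` clusters the sample columns,
#'   `"probes"` clusters the probe rows. Ignored for a matrix.
#' @return An object of classes `upgma` and `hclust` (so `plot()`,
#'   `stats::cutree()` and `ape::as.phylo()` apply), with `merge`,
#'   `height`, `order`, `labels` as in [stats::hclust()]. Use [tidy()]
#'   for the merge list as a tibble.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8.1),
#'            c = c(4, 3, 2, 1), d = c(8, 6.2, 4, 2))
#' tree <- upgma_cluster(m)
#' tidy(tree)
#' @export
upgma_cluster <- function(x, axis = c("samples", "probes")) {
  if (is.data.frame(x)) {
    axis <- match.arg(axis)
    expr <- .check_expression(x)
    vals <- as.matrix(expr[setdiff(names(expr), "probe_id")])
    if (axis == "samples") {
      m <- t(vals)
    } else {
      m <- vals
      rownames(m) <- expr$probe_id
    }
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("profile", seq_len(nrow(m)))
  }
  if (nrow(m) < 2) abort("need at least 2 profiles to cluster")
  if (ncol(m) < 2) abort("each profile needs at least 2 features")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance profile(s), correlation undefined: ",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(t(m))
  diag(d) <- 0
  .upgma_from_dist(d, rownames(m))
}

# average-linkage agglomeration by Lance-Williams updates on a full
# distance matrix; ties broken on sorted cluster-label pairs
.upgma_from_dist <- function(d, labels) {
  n <- length(labels)
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negatives are leaves
  clab <- labels               # label of a cluster = its smallest leaf label
  active <- rep(TRUE, n)
  work <- d
  diag(work) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    dmin <- min(work)
    cand <- which(work == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      a <- pmin(clab[cand[, 1]], clab[cand[, 2]])
      b <- pmax(clab[cand[, 1]], clab[cand[, 2]])
      cand <- cand[order(a, b)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmin
    upd <- (size[i] * work[i, ] + size[j] * work[j, ]) / (size[i] + size[j])
    work[i, ] <- upd
    work[, i] <- upd
    work[i, i] <- Inf
    work[j, ] <- Inf
    work[, j] <- Inf
    size[i] <- size[i] + size[j]
    clab[i] <- min(clab[i], clab[j])
    id[i] <- step
    active[j] <- FALSE
  }
  out <- structure(
    list(merge = merge, height = height,
         order = .dendrogram_order(merge),
         labels = labels, method = "average",
         dist.method = "one-minus-correlation",
         call = match.call()),
    class = c("upgma", "hclust"))
  out
}

# leaf order for plotting: left-to-right traversal of the merge tree
.dendrogram_order <- function(merge) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(nrow(merge))
}

#' @export
#' @method tidy upgma
tidy.upgma <- function(x, ...) {
  lab <- function(k) if (k < 0) x$labels[-k] else paste0("node", k)
  sizes <- integer(nrow(x$merge))
  size_of <- function(k) if (k < 0) 1L else sizes[k]
  for (i in seq_len(nrow(x$merge))) {
    sizes[i] <- size_of(x$merge[i, 1]) + size_of(x$merge[i, 2])
  }
  tibble::tibble(
    child1 = vapply(x$merge[, 1], lab, character(1)),
    child2 = vapply(x$merge[, 2], lab, character(1)),
    distance = x$height,
    size = sizes
  )
}
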