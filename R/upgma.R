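#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: repeatedly merge the
#' closest pair of clusters, averaging distances proportionally to cluster
#' sizes. The node joining two clusters sits at height d/2, so the tree is
#' ultrametric by construction. Ties in the closest-pair search are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member). Infinite distances
#' (the Nei `+Inf` sentinel for fixed opposite alleles) are refused with a
#' pointer to `cap_infinite`.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/column
#'   labels, or a [stats::dist].
#' @param cap_infinite optional finite value replacing infinite entries.
#' @return object of class `upgma`: `phylo` (an [ape] tree with branch
#'   lengths; root-to-tip height equals half the final merge distance),
#'   `newick` (the serialized tree), and `hclust` (a [stats::hclust]
#'   object whose heights are the merge distances, usable with
#'   [stats::cutree()] and [stats::cophenetic()]).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick  # ((A:1,B:1):2,C:3);
upgma <- function(d, cap_infinite = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  if (n < 2L) stop("need at least two taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (any(is.infinite(d))) {
    if (is.null(cap_infinite))
      stop("infinite distances present; supply cap_infinite to cap them")
    d[is.infinite(d)] <- cap_infinite
  }

  # active clusters: id < 0 => singleton -(row), > 0 => merge number
  active <- as.list(seq_len(n))        # member row indices per cluster
  ids <- -seq_len(n)                   # hclust-style ids
  labs <- labels                       # smallest member label per cluster
  sizes <- rep(1L, n)
  heights <- rep(0, n)                 # current node height (d/2 scale)
  newick <- labels
  dd <- d
  merge <- matrix(0L, n - 1L, 2L)
  merge_height <- numeric(n - 1L)

  cluster_dist <- function(i, j) dd[i, j]

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      dij <- cluster_dist(i, j)
      lab <- sort(c(labs[i], labs[j]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (lab[1L] < best$lab[1L] ||
            (lab[1L] == best$lab[1L] && lab[2L] < best$lab[2L])))) {
        best <- list(i = i, j = j, d = dij, lab = lab)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merge[step, ] <- c(ids[i], ids[j])
    merge_height[step] <- best$d
    bl_i <- h - heights[i]
    bl_j <- h - heights[j]
    # children ordered by smallest member label for a deterministic Newick
    first_i <- labs[i] <= labs[j]
    new_nwk <- sprintf("(%s:%s,%s:%s)",
                       newick[if (first_i) i else j],
                       format(if (first_i) bl_i else bl_j, digits = 15),
                       newick[if (first_i) j else i],
                       format(if (first_i) bl_j else bl_i, digits = 15))
    # proportional (arithmetic-mean) distance update
    keep <- setdiff(seq_len(m), c(i, j))
    new_d <- (sizes[i] * dd[i, keep] + sizes[j] * dd[j, keep]) /
      (sizes[i] + sizes[j])
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], new_d),
                c(new_d, 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    ids <- c(ids[keep], step)
    labs <- c(labs[keep], min(best$lab))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    heights <- c(heights[keep], h)
    newick <- c(newick[keep], new_nwk)
  }

  nwk <- paste0(newick[1L], ";")
  phylo <- ape::read.tree(text = nwk)
  hc <- structure(list(merge = merge, height = merge_height,
                       order = order_from_merge(merge, n),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  structure(list(phylo = phylo, newick = nwk, hclust = hc,
                 root_height = merge_height[n - 1L] / 2),
            class = "upgma")
}

# leaf ordering for a valid hclust object
order_from_merge <- function(merge, n) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1L]), walk(merge[id, 2L]))
  }
  walk(n - 1L)
}

#' @export
print.upgma <- function(x, ...) {
  cat("UPGMA tree with", length(x$phylo$tip.label),
      "tips; root height", format(x$root_height), "\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Ultrametricity check for a tree
#'
#' All root-to-tip path lengths of a UPGMA tree must be equal (within
#' tolerance).
#'
#' @param phylo an [ape] `phylo` tree with branch lengths.
#' @param tol tolerance on the height spread.
#' @return logical.
#' @export
is_ultrametric_tree <- function(phylo, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(phylo)
  tips <- seq_along(phylo$tip.label)
  diff(range(depths[tips])) <= tol
}
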