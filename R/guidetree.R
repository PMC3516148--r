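# Rooted binary guide trees from a distance matrix by average-linkage
# (UPGMA) agglomeration. Node heights are merge distance / 2, so the tree is
# ultrametric. Tie-breaking is deterministic: among minimum-distance pairs
# the lexicographically smallest (label_i, label_j) wins, where a cluster's
# label is the smallest original index it contains; a node's children are
# ordered by smallest leaf index.

new_gt_leaf <- function(i) list(leaf = i, height = 0, leaves = i)

new_gt_node <- function(a, b, height) {
  if (min(a$leaves) > min(b$leaves)) { tmp <- a; a <- b; b <- tmp }
  list(height = max(height, a$height, b$height),
       children = list(a, b),
       leaves = sort(c(a$leaves, b$leaves)))
}

is_gt_leaf <- function(node) !is.null(node$leaf)

#' Build a UPGMA guide tree from a distance matrix
#'
#' Average-linkage agglomerative clustering. The result is a rooted,
#' strictly binary, ultrametric tree whose leaves are the row indices of
#' `d`; each internal node carries a height equal to half the distance at
#' which its two clusters merged. Ties on the minimum pair distance are
#' broken deterministically (smallest cluster labels), so the topology is
#' invariant under permutation of the input.
#'
#' @param d A symmetric numeric matrix of pairwise distances with zero
#'   diagonal and at least two rows.
#' @return An object of class `guide_tree`; leaf labels are taken from
#'   `rownames(d)` when present.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' upgma(d)
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (k < 2L) stop("need at least 2 items to build a guide tree")
  if (ncol(d) != k || max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be square and symmetric")
  labels <- rownames(d)
  nodes <- lapply(seq_len(k), new_gt_leaf)
  lab <- seq_len(k)     # cluster label = smallest original index
  size <- rep(1L, k)
  D <- d
  active <- seq_len(k)
  while (length(active) > 1L) {
    m <- length(active)
    # minimum-distance pair; ties broken by smallest (label_i, label_j)
    U <- D
    U[lower.tri(U, diag = TRUE)] <- Inf
    bestd <- min(U)
    cand <- which(U <= bestd + 1e-15, arr.ind = TRUE)
    li <- pmin(lab[cand[, 1L]], lab[cand[, 2L]])
    lj <- pmax(lab[cand[, 1L]], lab[cand[, 2L]])
    pick <- order(li, lj)[1L]
    ii <- cand[pick, 1L]; jj <- cand[pick, 2L]
    bestd <- D[ii, jj]
    merged <- new_gt_node(nodes[[ii]], nodes[[jj]], bestd / 2)
    # UPGMA update: size-weighted average to every other cluster
    keep <- setdiff(seq_len(m), c(ii, jj))
    newd <- (size[ii] * D[ii, keep] + size[jj] * D[jj, keep]) /
      (size[ii] + size[jj])
    D <- if (length(keep))
      rbind(cbind(D[keep, keep, drop = FALSE], newd),
            c(newd, 0), deparse.level = 0L)
    else matrix(0, 1L, 1L)
    nodes <- c(nodes[keep], list(merged))
    lab <- c(lab[keep], min(lab[ii], lab[jj]))
    size <- c(size[keep], size[ii] + size[jj])
    active <- seq_len(length(nodes))
  }
  root <- nodes[[1L]]
  structure(root, class = "guide_tree", nleaves = k, labels = labels)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("Guide tree with", attr(x, "nleaves"), "tips; root height",
      signif(x$height, 4), "\n")
  cat(to_newick(x), "\n")
  invisible(x)
}

gt_find_parent <- function(node, leaf) {
  if (is_gt_leaf(node)) return(NULL)
  for (ci in 1:2) {
    child <- node$children[[ci]]
    if (is_gt_leaf(child) && child$leaf == leaf)
      return(list(parent = node, sibling = node$children[[3L - ci]]))
    if (leaf %in% child$leaves) return(gt_find_parent(child, leaf))
  }
  NULL
}

#' Leaf indices of a tip's sibling subtree
#'
#' Identifies the leaves of the subtree that is the sibling of the given
#' tip — i.e. the cluster the tip attaches to. Used during fragment
#' placement to select which backbone rows the fragment is aligned against;
#' everything above the attachment node leaves the frozen alignment
#' untouched and needs no computation.
#'
#' @param tree A [upgma()] guide tree.
#' @param leaf A leaf index present in the tree.
#' @return Sorted integer vector of leaf indices.
#' @export
attachment_split <- function(tree, leaf) {
  if (!(leaf %in% tree$leaves)) stop("leaf ", leaf, " not present in tree")
  hit <- gt_find_parent(tree, leaf)
  sort(hit$sibling$leaves)
}

#' Export a guide tree as a Newick string
#'
#' Branch lengths are parent height minus child height (leaves have height
#' 0), so path lengths reproduce the ultrametric distances.
#'
#' @param tree A `guide_tree`.
#' @param labels Optional character vector of tip labels (defaults to the
#'   distance-matrix rownames, or the leaf indices).
#' @return A Newick string terminated by `;`.
#' @export
to_newick <- function(tree, labels = NULL) {
  if (is.null(labels)) labels <- attr(tree, "labels")
  if (is.null(labels)) labels <- as.character(seq_len(attr(tree, "nleaves")))
  fmt <- function(x) sprintf("%.10g", x)
  rec <- function(node, parent_height) {
    bl <- fmt(parent_height - node$height)
    if (is_gt_leaf(node)) return(paste0(labels[node$leaf], ":", bl))
    paste0("(", rec(node$children[[1L]], node$height), ",",
           rec(node$children[[2L]], node$height), "):", bl)
  }
  if (is_gt_leaf(tree)) return(paste0(labels[tree$leaf], ";"))
  paste0("(", rec(tree$children[[1L]], tree$height), ",",
         rec(tree$children[[2L]], tree$height), ");")
}
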