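# Guide-tree-constrained progressive addition of full-length sequences.
# A distance matrix over all N + n sequences seeds a UPGMA guide tree; the
# tree is traversed in postorder. Subtrees made only of backbone rows (or of
# rows already merged into the backbone's coordinate system) need no
# computation; when a subtree of new sequences meets the backbone, its
# sub-alignment is aligned against the profile of that backbone subtree's
# rows taken over the full current column set, and any gap opened on the
# backbone side becomes a full gap column across every row, so the backbone
# columns are preserved exactly.

#' Add full-length sequences into an existing alignment
#'
#' Progressive alignment over a UPGMA guide tree with the existing
#' alignment's columns frozen: removing the new rows from the result and
#' dropping all-gap columns reproduces the input alignment byte for byte.
#' This strategy assumes the new sequences are full-length; for short
#' fragments use [add_fragments()], since distances among non-overlapping
#' fragments are mostly meaningless and degrade the guide tree.
#'
#' @param existing An `msa` object with at least 2 rows (the backbone).
#' @param new Named character vector of ungapped new sequences (names
#'   disjoint from the backbone ids).
#' @param mode Distance mode for the guide tree: `"6mer"` (fast,
#'   alignment-free) or `"dp"` (Smith-Waterman local alignment scores).
#' @param scheme A [scoring_scheme()]; guessed from the data when `NULL`.
#' @return An `msa` with the backbone rows first (original order) followed
#'   by the new sequences in input order.
#' @examples
#' bb <- alignment(c("a", "b"), c("ACGT", "ACGT"))
#' add_sequences(bb, c(x = "ACGGT"), mode = "6mer")
#' @export
add_sequences <- function(existing, new, mode = c("6mer", "dp"),
                          scheme = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(existing, "msa"))
  N <- length(existing$ids)
  n <- length(new)
  if (N < 2L) stop("the existing alignment must have at least 2 rows")
  if (n < 1L) stop("no new sequences to add")
  if (is.null(names(new)) || any(!nzchar(names(new))))
    stop("new sequences must be named")
  if (any(names(new) %in% existing$ids))
    stop("id collision between new sequences and the existing alignment: ",
         paste(intersect(names(new), existing$ids), collapse = ", "))
  scheme <- default_scheme(c(existing$rows, new), scheme)

  backbone <- degap(existing)
  d <- build_add_matrix(backbone, new, mode = mode, scheme = scheme)
  tree <- upgma(d)

  # global state: all rows currently in the backbone coordinate system
  st <- new.env(parent = emptyenv())
  st$ids <- existing$ids
  st$rows <- existing$rows

  anchor_floating <- function(anchor_ids, flt) {
    ga <- alignment(st$ids, st$rows)
    pA <- make_profile(ga, rows = anchor_ids, scheme = scheme)
    fa <- alignment(flt$ids, flt$rows)
    pF <- make_profile(fa, scheme = scheme)
    ap <- profile_align(pA, pF, scheme, terminal_free = "none")
    check_trace(ap$trace, ga$ncols, fa$ncols)
    st$rows <- expand_rows(st$rows, ap$trace[, 1L])
    st$ids <- c(st$ids, flt$ids)
    st$rows <- c(st$rows, expand_rows(flt$rows, ap$trace[, 2L]))
    invisible(NULL)
  }

  merge_floating <- function(a, b) {
    aa <- alignment(a$ids, a$rows)
    bb <- alignment(b$ids, b$rows)
    ap <- profile_align(make_profile(aa, scheme = scheme),
                        make_profile(bb, scheme = scheme),
                        scheme, terminal_free = "none")
    merged <- apply_trace(aa, bb, ap)
    list(kind = "floating", ids = merged$ids, rows = merged$rows)
  }

  all_ids <- c(existing$ids, names(new))
  visit <- function(node) {
    if (is_gt_leaf(node)) {
      i <- node$leaf
      if (i <= N) return(list(kind = "anchored", ids = existing$ids[i]))
      return(list(kind = "floating", ids = all_ids[i],
                  rows = unname(new[i - N])))
    }
    l <- visit(node$children[[1L]])
    r <- visit(node$children[[2L]])
    if (l$kind == "anchored" && r$kind == "anchored")
      return(list(kind = "anchored", ids = c(l$ids, r$ids)))
    if (l$kind == "floating" && r$kind == "floating")
      return(merge_floating(l, r))
    a <- if (l$kind == "anchored") l else r
    f <- if (l$kind == "anchored") r else l
    anchor_floating(a$ids, f)
    list(kind = "anchored", ids = c(a$ids, f$ids))
  }
  visit(tree)

  ord <- match(all_ids, st$ids)
  alignment(all_ids, st$rows[ord])
}
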