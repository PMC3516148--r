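# Independent per-fragment placement and the n-way merge. Each fragment is
# placed against the profile of the backbone subtree it attaches to in its
# own (N+1)-tip UPGMA tree; the result is reduced to a row over the original
# backbone columns plus insertion records (segments anchored at inter-column
# positions). Because each placement depends only on the backbone, its
# distance matrix and that single fragment, placements are pure per-fragment
# functions and can run in any order (or in parallel) with identical
# results; the merge step combines them, inserting corresponding gap columns
# and aligning same-anchor insertions to each other.

#' Construct a placed-fragment record
#'
#' @param id Fragment id.
#' @param row Gapped row over the original backbone columns (excluding the
#'   fragment's own insertions).
#' @param insertions List of insertion records, each a list with `anchor`
#'   (0-based inter-column position in original backbone coordinates: the
#'   segment is inserted before column `anchor + 1`) and `segment` (the
#'   inserted residues).
#' @param unplaceable Logical flag: `TRUE` when the fragment had no positive
#'   similarity to any backbone sequence and was aligned against the full
#'   alignment profile as a fallback.
#' @return An object of class `placed_fragment`.
#' @export
placed_fragment <- function(id, row, insertions = list(),
                            unplaceable = FALSE) {
  structure(list(id = id, row = row, insertions = insertions,
                 unplaceable = unplaceable),
            class = "placed_fragment")
}

#' @export
print.placed_fragment <- function(x, ...) {
  cat("Placed fragment '", x$id, "': ", length(x$insertions),
      " insertion(s)", if (x$unplaceable) " [unplaceable fallback]", "\n",
      sep = "")
  invisible(x)
}

# reduce a fragment-vs-backbone trace to (row, insertions); left = backbone
# columns, right = fragment residues
trace_to_placement <- function(id, frag, trace, ncols) {
  fr <- strsplit(frag, "", fixed = TRUE)[[1L]]
  row <- rep("-", ncols)
  insertions <- list()
  cur_anchor <- -1L
  cur_seg <- character(0L)
  consumed <- 0L
  flush <- function() {
    if (length(cur_seg))
      insertions[[length(insertions) + 1L]] <<-
        list(anchor = cur_anchor, segment = paste(cur_seg, collapse = ""))
    cur_seg <<- character(0L)
  }
  for (k in seq_len(nrow(trace))) {
    lf <- trace[k, 1L]; rt <- trace[k, 2L]
    if (lf == 0L) {                       # new residue between backbone cols
      if (length(cur_seg) == 0L) cur_anchor <- consumed
      cur_seg <- c(cur_seg, fr[rt])
    } else {
      flush()
      consumed <- consumed + 1L
      if (rt > 0L) row[lf] <- fr[rt]
    }
  }
  flush()
  placed_fragment(id, paste(row, collapse = ""), insertions)
}

place_against_rows <- function(existing, rows, frag_id, frag, scheme,
                               unplaceable = FALSE) {
  pA <- make_profile(existing, rows = rows, scheme = scheme)
  pF <- make_profile(alignment(frag_id, frag), scheme = scheme)
  ap <- profile_align(pA, pF, scheme, terminal_free = "q_side")
  out <- trace_to_placement(frag_id, frag, ap$trace, existing$ncols)
  out$unplaceable <- unplaceable
  out
}

#' Place one fragment against the existing alignment
#'
#' Builds an (N+1)-tip UPGMA tree from the backbone distance matrix plus the
#' fragment's N cross distances, takes the fragment's sibling subtree as its
#' attachment point, and aligns the fragment (with free terminal gaps on the
#' fragment side) against the profile of those backbone rows over the full
#' column set. Rows above the attachment are frozen and need no computation.
#' A fragment whose cross distances are all 1 (no similarity anywhere) is
#' flagged unplaceable and aligned against the full-alignment profile as a
#' fallback rather than dropped.
#'
#' @param existing An `msa` object (the backbone, N >= 2 rows).
#' @param backbone_dist N x N symmetric distance matrix over the backbone
#'   rows (in row order), e.g. from [build_addfrag_distances()].
#' @param frag A single named ungapped sequence (length-1 named character
#'   vector).
#' @param cross_distances Numeric vector of N distances between the
#'   backbone rows and the fragment.
#' @param scheme A [scoring_scheme()].
#' @return A [placed_fragment()] record in original backbone coordinates.
#' @export
place_fragment <- function(existing, backbone_dist, frag, cross_distances,
                           scheme = NULL) {
  stopifnot(inherits(existing, "msa"))
  N <- length(existing$ids)
  if (length(cross_distances) != N)
    stop("cross_distances must have one entry per backbone row")
  if (length(frag) != 1L || is.null(names(frag)))
    stop("frag must be a single named sequence")
  scheme <- default_scheme(c(existing$rows, frag), scheme)
  if (all(cross_distances >= 1)) {
    message("fragment '", names(frag),
            "' has no similarity to the backbone; aligned against the ",
            "full-alignment profile")
    return(place_against_rows(existing, existing$ids, names(frag),
                              unname(frag), scheme, unplaceable = TRUE))
  }
  m <- rbind(cbind(backbone_dist, cross_distances),
             c(cross_distances, 0), deparse.level = 0L)
  tree <- upgma(m)
  sib <- attachment_split(tree, N + 1L)
  place_against_rows(existing, existing$ids[sib], names(frag),
                     unname(frag), scheme)
}

#' Merge independent fragment placements into one alignment
#'
#' Combines per-fragment placements: if no fragment inserted residues into
#' the backbone, no new gap is needed; where one fragment inserted a
#' segment, a corresponding gap block is inserted into the backbone rows and
#' into every other fragment; where several fragments inserted segments at
#' the same inter-column position, the segments are aligned to each other
#' (progressive profile alignment, joined in input order) and the resulting
#' block is inserted once. Backbone columns appear in their original order,
#' interleaved with the insert blocks.
#'
#' @param existing An `msa` object (the backbone).
#' @param placed List of [placed_fragment()] records over `existing`'s
#'   coordinates.
#' @param scheme A [scoring_scheme()] (used to align same-anchor segments).
#' @return An `msa` with the backbone rows first, then one row per fragment
#'   in input order.
#' @export
merge_placements <- function(existing, placed, scheme = NULL) {
  stopifnot(inherits(existing, "msa"))
  scheme <- default_scheme(existing$rows, scheme)
  nfrag <- length(placed)
  frag_ids <- vapply(placed, function(p) p$id, "")
  ncols <- existing$ncols
  for (p in placed) {
    for (ins in p$insertions) {
      if (ins$anchor < 0L || ins$anchor > ncols)
        stop("insertion anchor ", ins$anchor, " of fragment '", p$id,
             "' is outside 0..", ncols)
      if (!nzchar(ins$segment)) stop("empty insertion segment")
    }
    if (nchar(p$row) != ncols)
      stop("placed row of '", p$id, "' does not match the backbone columns")
  }

  # group insertions by anchor, keeping fragment input order within a group
  anchors <- sort(unique(unlist(lapply(placed, function(p)
    vapply(p$insertions, function(i) i$anchor, 0L)))))
  blocks <- list()  # per anchor: list(width, rows = named segment rows)
  for (a in anchors) {
    segs <- list()
    for (p in placed) {
      for (ins in p$insertions)
        if (ins$anchor == a) segs[[p$id]] <- ins$segment
    }
    if (length(segs) == 1L) {
      blk <- alignment(names(segs), segs[[1L]])
    } else {
      blk <- alignment(names(segs)[1L], segs[[1L]])
      for (k in 2L:length(segs)) {
        nxt <- alignment(names(segs)[k], segs[[k]])
        ap <- profile_align(make_profile(blk, scheme = scheme),
                            make_profile(nxt, scheme = scheme),
                            scheme, terminal_free = "none")
        blk <- apply_trace(blk, nxt, ap)
      }
    }
    blocks[[as.character(a)]] <- blk
  }

  em <- aln_matrix(existing)
  fm <- if (nfrag)
    do.call(rbind, lapply(placed, function(p)
      strsplit(p$row, "", fixed = TRUE)[[1L]]))
  else matrix(character(), 0L, ncols)
  if (ncols == 0L) fm <- matrix(character(), nfrag, 0L)

  pieces_e <- list(); pieces_f <- list(); pi <- 0L
  emit <- function(e, f) {
    pi <<- pi + 1L
    pieces_e[[pi]] <<- e
    pieces_f[[pi]] <<- f
  }
  for (a in 0L:ncols) {
    key <- as.character(a)
    if (!is.null(blocks[[key]])) {
      blk <- blocks[[key]]
      w <- blk$ncols
      fblk <- matrix("-", nfrag, w)
      hit <- match(blk$ids, frag_ids)
      bm <- aln_matrix(blk)
      fblk[hit, ] <- bm
      emit(matrix("-", length(existing$ids), w), fblk)
    }
    if (a < ncols)
      emit(em[, a + 1L, drop = FALSE], fm[, a + 1L, drop = FALSE])
  }
  eout <- do.call(cbind, pieces_e)
  fout <- do.call(cbind, pieces_f)
  out <- rbind(eout, fout)
  matrix_aln(c(existing$ids, frag_ids), out)
}

#' Compute independent placements for a set of fragments
#'
#' The per-fragment records behind [add_fragments()]: each is a pure
#' function of the backbone, the backbone distance matrix and that fragment
#' alone, so placing any subset of the fragments yields identical records.
#'
#' @inheritParams add_fragments
#' @return Named list of [placed_fragment()] records.
#' @export
fragment_placements <- function(existing, new, scheme = NULL) {
  stopifnot(inherits(existing, "msa"))
  if (length(new) < 1L) stop("no fragments to place")
  if (is.null(names(new)) || any(!nzchar(names(new))))
    stop("fragments must be named")
  if (any(names(new) %in% existing$ids))
    stop("id collision between fragments and the existing alignment: ",
         paste(intersect(names(new), existing$ids), collapse = ", "))
  scheme <- default_scheme(c(existing$rows, new), scheme)
  dd <- build_addfrag_distances(degap(existing), new, scheme = scheme)
  out <- vector("list", length(new))
  names(out) <- names(new)
  for (j in seq_along(new)) {
    out[[j]] <- place_fragment(existing, dd$backbone, new[j],
                               dd$cross[, j], scheme)
  }
  out
}

#' Add fragmentary sequences into an existing alignment
#'
#' The fragment-placement pipeline: backbone distances, one local alignment
#' per backbone-fragment pair, an (N+1)-tip guide tree and placement per
#' fragment — each fragment handled independently of the others — followed
#' by a merge that inserts corresponding gap columns and aligns same-anchor
#' insertions to each other. The existing alignment's columns are preserved
#' exactly.
#'
#' @param existing An `msa` object with at least 2 rows.
#' @param new Named character vector of ungapped fragments (n >= 1), names
#'   disjoint from the backbone ids.
#' @param scheme A [scoring_scheme()]; guessed from the data when `NULL`.
#' @return An `msa` with backbone rows first, then one row per fragment in
#'   input order. Ids of fragments that could not be placed by similarity
#'   (aligned against the full profile as a fallback) are available in
#'   `attr(result, "unplaceable")`.
#' @examples
#' bb <- alignment(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
#' add_fragments(bb, c(f1 = "GTAC"))
#' @export
add_fragments <- function(existing, new, scheme = NULL) {
  scheme <- default_scheme(c(existing$rows, new), scheme)
  placed <- fragment_placements(existing, new, scheme)
  out <- merge_placements(existing, placed, scheme)
  unpl <- names(placed)[vapply(placed, function(p) p$unplaceable, TRUE)]
  attr(out, "unplaceable") <- unpl
  out
}
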