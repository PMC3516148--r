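# Pairwise similarity and distances: shared 6-mers and Smith-Waterman local
# alignment, both converted to distances in [0, 1] by d = 1 - S / min(self),
# plus assembly of the distance matrices the two add strategies need.

#' Create a scoring scheme
#'
#' Bundles the substitution scores and affine gap penalties used by all
#' alignment routines. A gap of length k costs `gap_open + (k-1) *
#' gap_extend`. For nucleotide data a match/mismatch matrix is built; any
#' residue outside `ACGT` (including `N` and IUPAC ambiguity codes) scores
#' `wildcard` against everything. For protein data BLOSUM62 is used and `X`
#' is the wildcard.
#'
#' @param moltype `"nucleotide"` or `"protein"`.
#' @param match Match score (nucleotide only); must be positive.
#' @param mismatch Mismatch score (nucleotide only); must be non-positive.
#' @param gap_open Penalty for the first position of a gap (non-negative).
#' @param gap_extend Penalty for each further gap position; must satisfy
#'   `gap_open >= gap_extend >= 0`.
#' @param wildcard Score for any pairing involving a wildcard residue.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme("protein")
#' @export
scoring_scheme <- function(moltype = c("nucleotide", "protein"),
                           match = 2, mismatch = -1,
                           gap_open = if (moltype[1L] == "protein") 11 else 4,
                           gap_extend = 1, wildcard = 0) {
  moltype <- match.arg(moltype)
  if (match <= 0) stop("match score must be positive")
  if (mismatch > 0) stop("mismatch score must be <= 0")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  if (moltype == "nucleotide") {
    core <- c("A", "C", "G", "T")
    alphabet <- c(core, "N")
    sm <- matrix(mismatch, 5L, 5L, dimnames = list(alphabet, alphabet))
    diag(sm) <- match
    sm["N", ] <- wildcard
    sm[, "N"] <- wildcard
  } else {
    core <- AA_CHARS[AA_CHARS != "X"]
    alphabet <- c(core, "X")
    b62 <- get_blosum62()
    sm <- matrix(wildcard, 21L, 21L, dimnames = list(alphabet, alphabet))
    sm[core, core] <- b62[core, core]
  }
  structure(list(moltype = moltype, alphabet = alphabet, submat = sm,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 wildcard = wildcard),
            class = "scoring_scheme")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

default_scheme <- function(x, scheme = NULL) {
  if (!is.null(scheme)) return(scheme)
  scoring_scheme(guess_moltype(x))
}

# residues -> 1-based codes into scheme$submat; anything outside the core
# alphabet maps to the wildcard code (last)
code_seq <- function(s, scheme) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(ch, scheme$alphabet)
  idx[is.na(idx)] <- length(scheme$alphabet)
  idx
}

kmer_table <- function(s, k = 6L, core) {
  n <- nchar(s)
  if (n < k) return(integer(0L))
  w <- substring(s, 1:(n - k + 1L), k:n)
  pat <- paste0("[^", paste(core, collapse = ""), "]")
  w <- w[!grepl(pat, w)]
  if (length(w) == 0L) return(integer(0L))
  table(w)
}

#' Number of shared 6-mers between two sequences
#'
#' Counts, over distinct 6-mers, the minimum of the two occurrence counts
#' (multiset intersection). 6-mers containing a wildcard residue are
#' skipped. Returns 0 if either sequence is shorter than 6.
#'
#' @param a,b Ungapped residue strings.
#' @param moltype `"nucleotide"`, `"protein"`, or `NULL` to guess.
#' @return A non-negative integer count.
#' @examples
#' shared_6mer_count("ACGTACGTAC", "ACGTACGTAC")
#' @export
shared_6mer_count <- function(a, b, moltype = NULL) {
  if (is.null(moltype)) moltype <- guess_moltype(c(a, b))
  core <- if (moltype == "nucleotide") c("A", "C", "G", "T")
          else AA_CHARS[AA_CHARS != "X"]
  ta <- kmer_table(a, 6L, core)
  tb <- kmer_table(b, 6L, core)
  if (length(ta) == 0L || length(tb) == 0L) return(0L)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0L) return(0L)
  as.integer(sum(pmin(as.integer(ta[common]), as.integer(tb[common]))))
}

#' 6-mer distance between two sequences
#'
#' `1 - shared / min(T(a), T(b))` where `T(s) = max(0, nchar(s) - 5)` is the
#' number of 6-mer positions; the distance is 1 when either sequence has no
#' 6-mers. Always in `[0, 1]`.
#'
#' @inheritParams shared_6mer_count
#' @return A distance in `[0, 1]`.
#' @export
sixmer_distance <- function(a, b, moltype = NULL) {
  ta <- max(0L, nchar(a) - 5L)
  tb <- max(0L, nchar(b) - 5L)
  denom <- min(ta, tb)
  if (denom == 0L) return(1)
  d <- 1 - shared_6mer_count(a, b, moltype) / denom
  min(max(d, 0), 1)
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment with affine gaps (Gotoh recurrences, score
#' floored at zero). Only the single best hit is reported; ties on the
#' optimal score are broken by the smallest end coordinate in `a`, then in
#' `b`.
#'
#' @param a,b Ungapped residue strings.
#' @param scheme A [scoring_scheme()]; defaults to one guessed from the
#'   residues.
#' @return An object of class `local_hit`: a list with `score` and
#'   half-open, 0-based residue intervals `a_range` and `b_range`
#'   (`c(start, end)` with `end - start` residues); both intervals are empty
#'   when `score == 0`.
#' @examples
#' smith_waterman("ACGTT", "CGT")
#' @export
smith_waterman <- function(a, b, scheme = NULL) {
  scheme <- default_scheme(c(a, b), scheme)
  res <- sw_align_cpp(code_seq(a, scheme), code_seq(b, scheme),
                      scheme$submat, scheme$gap_open, scheme$gap_extend)
  if (res$score <= 0)
    return(structure(list(score = 0, a_range = c(0L, 0L),
                          b_range = c(0L, 0L)), class = "local_hit"))
  structure(list(score = res$score,
                 a_range = c(res$a_start - 1L, res$a_end),
                 b_range = c(res$b_start - 1L, res$b_end)),
            class = "local_hit")
}

#' @export
print.local_hit <- function(x, ...) {
  cat("Local hit: score ", x$score, ", a[", x$a_range[1L], ",",
      x$a_range[2L], ") x b[", x$b_range[1L], ",", x$b_range[2L], ")\n",
      sep = "")
  invisible(x)
}

sw_score <- function(ca, cb, scheme) {
  sw_align_cpp(ca, cb, scheme$submat, scheme$gap_open, scheme$gap_extend)$score
}

#' Local-alignment distance between two sequences
#'
#' `1 - S(a,b) / min(S(a,a), S(b,b))`, clamped to `[0, 1]`, where `S` is the
#' Smith-Waterman score. When no positive-scoring local alignment exists the
#' distance is set to 1.
#'
#' @inheritParams smith_waterman
#' @return A distance in `[0, 1]`; 0 for identical sequences.
#' @export
dp_distance <- function(a, b, scheme = NULL) {
  scheme <- default_scheme(c(a, b), scheme)
  ca <- code_seq(a, scheme); cb <- code_seq(b, scheme)
  sab <- sw_score(ca, cb, scheme)
  if (sab <= 0) return(1)
  denom <- min(sw_score(ca, ca, scheme), sw_score(cb, cb, scheme))
  if (denom <= 0) return(1)
  min(max(1 - sab / denom, 0), 1)
}

#' Distance matrix over backbone and new sequences
#'
#' Builds the full `(N + n) x (N + n)` distance matrix over the backbone
#' sequences (first, in order) and the new sequences (after, in order) used
#' to construct the guide tree for [add_sequences()].
#'
#' @param existing Named character vector of the N ungapped backbone
#'   sequences (N >= 2).
#' @param new Named character vector of new sequences (may be empty).
#' @param mode Distance mode: `"6mer"` (shared 6-mer count) or `"dp"`
#'   (Smith-Waterman score), both converted to distances in `[0, 1]`.
#' @param scheme A [scoring_scheme()] (used by the `"dp"` mode).
#' @return A symmetric numeric matrix with zero diagonal and dimnames taken
#'   from the sequence names.
#' @export
build_add_matrix <- function(existing, new = character(0L),
                             mode = c("6mer", "dp"), scheme = NULL) {
  mode <- match.arg(mode)
  if (length(existing) < 2L) stop("need at least 2 backbone sequences")
  seqs <- c(existing, new)
  scheme <- default_scheme(seqs, scheme)
  k <- length(seqs)
  d <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
  if (mode == "6mer") {
    core <- if (scheme$moltype == "nucleotide") c("A", "C", "G", "T")
            else AA_CHARS[AA_CHARS != "X"]
    tabs <- lapply(seqs, kmer_table, k = 6L, core = core)
    tt <- pmax(0L, nchar(seqs) - 5L)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        denom <- min(tt[i], tt[j])
        if (denom == 0L) { d[i, j] <- d[j, i] <- 1; next }
        ta <- tabs[[i]]; tb <- tabs[[j]]
        common <- intersect(names(ta), names(tb))
        shared <- if (length(common)) sum(pmin(as.integer(ta[common]),
                                               as.integer(tb[common]))) else 0
        d[i, j] <- d[j, i] <- min(max(1 - shared / denom, 0), 1)
      }
    }
  } else {
    codes <- lapply(seqs, code_seq, scheme = scheme)
    self <- vapply(codes, function(cc) sw_score(cc, cc, scheme), 0)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        sab <- sw_score(codes[[i]], codes[[j]], scheme)
        denom <- min(self[i], self[j])
        d[i, j] <- d[j, i] <-
          if (sab <= 0 || denom <= 0) 1 else min(max(1 - sab / denom, 0), 1)
      }
    }
  }
  d
}

#' Distances for independent fragment placement
#'
#' Computes the `N x N` backbone distance matrix and the `N x n` matrix of
#' backbone-to-fragment distances (one Smith-Waterman local alignment per
#' pair; when no alignment is found the distance is set to 1). No
#' fragment-fragment distances are computed: fragments are placed
#' independently of one another.
#'
#' @param existing Named character vector of the N ungapped backbone
#'   sequences (N >= 2).
#' @param new Named character vector of the n fragments (n >= 1).
#' @param scheme A [scoring_scheme()].
#' @return A list with `backbone` (N x N symmetric matrix) and `cross`
#'   (N x n matrix, columns named by fragment id).
#' @export
build_addfrag_distances <- function(existing, new, scheme = NULL) {
  if (length(existing) < 2L) stop("need at least 2 backbone sequences")
  if (length(new) < 1L) stop("need at least 1 new sequence")
  scheme <- default_scheme(c(existing, new), scheme)
  backbone <- build_add_matrix(existing, character(0L), mode = "dp",
                               scheme = scheme)
  ce <- lapply(existing, code_seq, scheme = scheme)
  cn <- lapply(new, code_seq, scheme = scheme)
  selfe <- vapply(ce, function(cc) sw_score(cc, cc, scheme), 0)
  selfn <- vapply(cn, function(cc) sw_score(cc, cc, scheme), 0)
  cross <- matrix(1, length(existing), length(new),
                  dimnames = list(names(existing), names(new)))
  for (i in seq_along(existing)) {
    for (j in seq_along(new)) {
      sab <- sw_score(ce[[i]], cn[[j]], scheme)
      denom <- min(selfe[i], selfn[j])
      cross[i, j] <-
        if (sab <= 0 || denom <= 0) 1 else min(max(1 - sab / denom, 0), 1)
    }
  }
  list(backbone = backbone, cross = cross)
}
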