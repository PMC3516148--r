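# Profile construction and affine-gap global profile-profile DP: the
# primitive executed at every progressive node. A profile stores, per
# column, the residue frequency vector over the scoring alphabet plus the
# gap fraction (all rows weighted uniformly). The column-column score is the
# expected pairwise substitution score sum_x sum_y f_p(x) f_q(y) s(x, y);
# gap fractions do not enter the substitution term but discount gap
# penalties: a gap placed against a column costs penalty * (1 - gap
# fraction of that column).

#' Build a profile from alignment rows
#'
#' @param a An `msa` object.
#' @param rows Character vector of row ids to include (default: all rows).
#'   Frequencies are computed over these rows only, but across all columns
#'   of `a`.
#' @param scheme A [scoring_scheme()] defining the alphabet; wildcard and
#'   ambiguity residues are pooled into the wildcard letter.
#' @return An object of class `msa_profile` with elements `freq` (alphabet
#'   x ncols matrix), `gap` (per-column gap fraction), `ncols`, `nrow`,
#'   `ids`, `alphabet`.
#' @export
make_profile <- function(a, rows = NULL, scheme = NULL) {
  stopifnot(inherits(a, "msa"))
  scheme <- default_scheme(a$rows, scheme)
  if (is.null(rows)) rows <- a$ids
  idx <- match(rows, a$ids)
  if (anyNA(idx))
    stop("unknown row id(s): ", paste(rows[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) stop("profile needs at least one row")
  alpha <- scheme$alphabet
  K <- length(alpha)
  m <- aln_matrix(a)[idx, , drop = FALSE]
  codes <- match(m, alpha)                     # NA for gaps and wildcards
  codes[is.na(codes) & m != "-"] <- K          # pool unknowns as wildcard
  codes[m == "-"] <- K + 1L                    # gap bucket
  dim(codes) <- dim(m)
  nr <- length(idx)
  counts <- apply(codes, 2L, tabulate, nbins = K + 1L)
  if (a$ncols == 0L) counts <- matrix(0, K + 1L, 0L)
  freq <- counts / nr
  rownames(freq) <- c(alpha, "-")
  structure(list(freq = freq[seq_len(K), , drop = FALSE],
                 gap = freq[K + 1L, ],
                 ncols = a$ncols, nrow = nr, ids = a$ids[idx],
                 alphabet = alpha),
            class = "msa_profile")
}

#' Globally align two profiles
#'
#' Affine-gap global dynamic programming over profile columns. With
#' `terminal_free = "q_side"` leading and trailing gaps in `q` carry no
#' penalty, which is the policy used when `q` is a fragment that covers only
#' part of `p`'s span; `"both"` frees terminal gaps on both sides; `"none"`
#' (the default) penalises all gaps, appropriate for full-length sequences.
#' Tie-breaking is deterministic: prefer a column match, then a gap in `q`,
#' then a gap in `p`.
#'
#' @param p,q `msa_profile` objects over the same alphabet.
#' @param scheme A [scoring_scheme()].
#' @param terminal_free Terminal gap policy: `"none"`, `"q_side"` or
#'   `"both"`.
#' @return An object of class `aligned_pair`: a list with `score` and
#'   `trace`, a 2-column integer matrix of (left column, right column)
#'   steps where 0 denotes a gap; non-zero entries in each column of the
#'   trace run 1..ncols in order.
#' @export
profile_align <- function(p, q, scheme = NULL,
                          terminal_free = c("none", "q_side", "both")) {
  terminal_free <- match.arg(terminal_free)
  stopifnot(inherits(p, "msa_profile"), inherits(q, "msa_profile"))
  if (p$ncols == 0L || q$ncols == 0L) stop("profiles must be non-empty")
  if (!identical(p$alphabet, q$alphabet))
    stop("profiles built over different alphabets")
  if (is.null(scheme)) scheme <- scoring_scheme(
    if (length(p$alphabet) == 5L) "nucleotide" else "protein")
  cs <- crossprod(p$freq, scheme$submat %*% q$freq)
  tf <- match(terminal_free, c("none", "q_side", "both")) - 1L
  res <- profile_dp_cpp(cs, p$gap, q$gap,
                        scheme$gap_open, scheme$gap_extend, tf)
  structure(list(score = res$score,
                 trace = cbind(left = res$left, right = res$right)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("Profile alignment: score ", signif(x$score, 6), ", ",
      nrow(x$trace), " columns (", sum(x$trace[, 1L] == 0L),
      " new on left, ", sum(x$trace[, 2L] == 0L), " on right)\n", sep = "")
  invisible(x)
}

# expand gapped rows according to one side of a trace: idx has one entry per
# output column, 0 meaning "insert a gap column here"
expand_rows <- function(rows, idx) {
  if (length(rows) == 0L) return(rows)
  n <- length(idx)
  nz <- idx > 0L
  m <- matrix("-", nrow = length(rows), ncol = n)
  src <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (is.null(src)) src <- matrix(character(), length(rows), 0L)
  m[, nz] <- src[, idx[nz], drop = FALSE]
  apply(m, 1L, paste, collapse = "")
}

check_trace <- function(trace, nleft, nright) {
  lf <- trace[, 1L][trace[, 1L] > 0L]
  rt <- trace[, 2L][trace[, 2L] > 0L]
  if (!identical(as.integer(lf), seq_len(nleft)))
    stop("trace does not cover the left alignment's ", nleft, " columns")
  if (!identical(as.integer(rt), seq_len(nright)))
    stop("trace does not cover the right alignment's ", nright, " columns")
}

#' Merge two alignments along a column trace
#'
#' Materialises a [profile_align()] result: wherever the trace has a gap on
#' the left, a full gap column is inserted into every row of `base`
#' (symmetrically for `other`), and the expanded row sets are concatenated
#' (`base` rows first). The ungapped content of every row is unchanged.
#'
#' @param base,other `msa` objects.
#' @param pair An `aligned_pair` whose trace covers `base$ncols` left
#'   columns and `other$ncols` right columns.
#' @return An `msa` with `nrow(base) + nrow(other)` rows.
#' @export
apply_trace <- function(base, other, pair) {
  stopifnot(inherits(base, "msa"), inherits(other, "msa"))
  trace <- if (inherits(pair, "aligned_pair")) pair$trace else pair
  check_trace(trace, base$ncols, other$ncols)
  alignment(c(base$ids, other$ids),
            c(expand_rows(base$rows, trace[, 1L]),
              expand_rows(other$rows, trace[, 2L])))
}
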