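# Data model: an alignment is an S3 object of class "msa" holding parallel
# vectors of ids and equal-length gapped rows; unaligned sequences travel as
# a named character vector of ungapped residue strings. '-' is the canonical
# gap; '.' is accepted on input only; case-insensitive input, uppercase
# canonical; U is normalised to T for nucleotide data.

NUC_CHARS <- c("A", "C", "G", "T", "U", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of gapped rows (gap character `-`), all of
#'   the same length, parallel to `ids`.
#' @return An object of class `msa` with elements `ids`, `rows` and `ncols`.
#' @examples
#' alignment(c("a", "b"), c("AC-GT", "ACTGT"))
#' @export
alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (length(ids) != length(rows))
    stop("ids and rows must have the same length")
  if (length(rows) == 0L)
    stop("an alignment needs at least one row")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nc <- nchar(rows)
  if (any(nc != nc[1L])) {
    bad <- ids[which(nc != nc[1L])[1L]]
    stop("ragged alignment: row '", bad, "' has ", nc[nc != nc[1L]][1L],
         " columns, expected ", nc[1L])
  }
  structure(list(ids = ids, rows = unname(rows), ncols = nc[1L]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " rows x ",
      x$ncols, " columns\n", sep = "")
  show <- head(seq_along(x$ids), 10L)
  w <- min(x$ncols, 60L)
  for (i in show)
    cat(sprintf("  %-12s %s%s\n", x$ids[i], substr(x$rows[i], 1L, w),
                if (x$ncols > w) "..." else ""))
  if (length(x$ids) > 10L) cat("  ...\n")
  invisible(x)
}

#' Remove gap characters from sequences or alignment rows
#'
#' @param x A character vector of (possibly gapped) sequences, or an `msa`
#'   object.
#' @return For a character vector, the vector with all `-` removed (names
#'   preserved); for an `msa`, a named character vector of ungapped residues.
#' @examples
#' degap(c(a = "AC-GT"))
#' @export
degap <- function(x) {
  if (inherits(x, "msa")) {
    out <- gsub("-", "", x$rows, fixed = TRUE)
    names(out) <- x$ids
    return(out)
  }
  out <- gsub("-", "", x, fixed = TRUE)
  names(out) <- names(x)
  out
}

# alignment rows as a character matrix (rows x columns)
aln_matrix <- function(a) {
  if (a$ncols == 0L)
    return(matrix(character(), nrow = length(a$rows), ncol = 0L))
  m <- matrix("", nrow = length(a$rows), ncol = a$ncols)
  sp <- strsplit(a$rows, "", fixed = TRUE)
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  m
}

matrix_aln <- function(ids, m) {
  rows <- if (ncol(m) == 0L) rep("", nrow(m)) else
    apply(m, 1L, paste, collapse = "")
  alignment(ids, rows)
}

guess_moltype <- function(x) {
  chars <- unique(strsplit(paste(toupper(x), collapse = ""), "")[[1L]])
  chars <- setdiff(chars, c("-", "."))
  if (length(chars) == 0L || all(chars %in% NUC_CHARS)) "nucleotide"
  else "protein"
}

normalize_residues <- function(x, moltype) {
  x <- toupper(x)
  x <- gsub(".", "-", x, fixed = TRUE)
  if (moltype == "nucleotide") x <- chartr("U", "T", x)
  x
}

#' Read sequences or an alignment from a FASTA file
#'
#' Lowercase residues are converted to uppercase, `.` gaps to `-`, and `U`
#' to `T` for nucleotide data. Identifiers are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, records must all have the same length and an
#'   `msa` object is returned; otherwise gaps are stripped and a named
#'   character vector of ungapped sequences is returned.
#' @param moltype `"nucleotide"`, `"protein"`, or `NULL` to guess from the
#'   residues.
#' @return An `msa` object (`aligned = TRUE`) or a named character vector.
#' @export
read_fasta <- function(path, aligned = FALSE, moltype = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (is.null(moltype)) moltype <- guess_moltype(seqs)
  seqs <- normalize_residues(seqs, moltype)
  if (aligned) {
    nc <- nchar(seqs)
    if (any(nc != nc[1L])) {
      bad <- ids[which(nc != nc[1L])[1L]]
      stop("ragged alignment in ", path, ": record '", bad, "'")
    }
    a <- alignment(ids, seqs)
    attr(a, "moltype") <- moltype
    a
  } else {
    out <- gsub("-", "", seqs, fixed = TRUE)
    if (any(!nzchar(out)))
      stop("empty sequence: ", ids[which(!nzchar(out))[1L]])
    names(out) <- ids
    attr(out, "moltype") <- moltype
    out
  }
}

fasta_lines <- function(ids, rows, width = 60L) {
  out <- character(0L)
  for (i in seq_along(ids)) {
    s <- rows[i]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    out <- c(out, paste0(">", ids[i]),
             substring(s, starts, pmin(starts + width - 1L, n)))
  }
  out
}

#' Write sequences or an alignment to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns. Reading the file back with
#' [read_fasta()] reproduces the input exactly.
#'
#' @param x An `msa` object or a named character vector of sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "msa")) {
    ids <- x$ids; rows <- x$rows
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    ids <- names(x); rows <- as.character(x)
  }
  if (length(ids) == 0L) stop("refusing to write an empty FASTA file")
  set <- Biostrings::BStringSet(stats::setNames(rows, ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Drop columns consisting entirely of gaps
#'
#' @param a An `msa` object.
#' @return An `msa` with every all-gap column removed; the relative order of
#'   the remaining columns (and the ungapped content of every row) is
#'   unchanged.
#' @examples
#' drop_allgap_columns(alignment(c("a", "b"), c("A--C", "T--G")))
#' @export
drop_allgap_columns <- function(a) {
  stopifnot(inherits(a, "msa"))
  m <- aln_matrix(a)
  keep <- colSums(m != "-") > 0L
  matrix_aln(a$ids, m[, keep, drop = FALSE])
}
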