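# Independent oracles used to validate the DP kernels and the accuracy
# statistic. These deliberately use different algorithmic formulations than
# the implementations they check (exhaustive enumeration / plain-R DP over
# all substring pairs / quadratic residue-pair scans).

NT4 <- c("A", "C", "G", "T")

# internal helpers reused by the oracles
aln_matrix <- alnadd:::aln_matrix
is_gt_leaf <- alnadd:::is_gt_leaf

# best local affine-gap score as the maximum, over ALL substring pairs, of a
# plain-R global three-state alignment of those substrings (floored at 0)
oracle_local_score <- function(a, b, scheme) {
  ca <- match(strsplit(a, "")[[1L]], scheme$alphabet)
  cb <- match(strsplit(b, "")[[1L]], scheme$alphabet)
  ca[is.na(ca)] <- length(scheme$alphabet)
  cb[is.na(cb)] <- length(scheme$alphabet)
  sm <- scheme$submat
  go <- scheme$gap_open; ge <- scheme$gap_extend
  global_score <- function(x, y) {
    lx <- length(x); ly <- length(y)
    M <- matrix(-Inf, lx + 1L, ly + 1L)
    X <- matrix(-Inf, lx + 1L, ly + 1L)
    Y <- matrix(-Inf, lx + 1L, ly + 1L)
    M[1L, 1L] <- 0
    for (i in seq_len(lx))
      X[i + 1L, 1L] <- (if (i == 1L) M[1L, 1L] - go else X[i, 1L] - ge)
    for (j in seq_len(ly))
      Y[1L, j + 1L] <- (if (j == 1L) M[1L, 1L] - go else Y[1L, j] - ge)
    for (i in seq_len(lx)) {
      for (j in seq_len(ly)) {
        M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) +
          sm[x[i], y[j]]
        X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go, X[i, j + 1L] - ge,
                                 Y[i, j + 1L] - go)
        Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go, X[i + 1L, j] - go,
                                 Y[i + 1L, j] - ge)
      }
    }
    max(M[lx + 1L, ly + 1L], X[lx + 1L, ly + 1L], Y[lx + 1L, ly + 1L])
  }
  best <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca))
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb))
      best <- max(best, global_score(ca[i1:i2], cb[j1:j2]))
  best
}

# score one explicit column trace under the profile cost model: expected
# substitution score on matches; gap runs cost open for their first column
# and extend afterwards, each scaled by (1 - gap fraction of the consumed
# column); with the q_side policy, gap-in-q runs lying before the first or
# after the last q column are free
score_trace_oracle <- function(trace, p, q, scheme, terminal_free) {
  cs <- matrix(0, p$ncols, q$ncols)
  for (i in seq_len(p$ncols)) for (j in seq_len(q$ncols))
    cs[i, j] <- sum(outer(p$freq[, i], q$freq[, j]) * scheme$submat)
  freeq <- terminal_free %in% c("q_side", "both")
  freep <- terminal_free == "both"
  go <- scheme$gap_open; ge <- scheme$gap_extend
  total <- 0; prev <- "M"; icons <- 0L; jcons <- 0L
  for (k in seq_len(nrow(trace))) {
    lf <- trace[k, 1L]; rt <- trace[k, 2L]
    if (lf > 0L && rt > 0L) {
      total <- total + cs[lf, rt]; prev <- "M"
      icons <- icons + 1L; jcons <- jcons + 1L
    } else if (lf > 0L) {
      w <- 1 - p$gap[lf]
      free <- freeq && (jcons == 0L || jcons == q$ncols)
      if (!free) total <- total - (if (prev == "X") ge else go) * w
      prev <- "X"; icons <- icons + 1L
    } else {
      w <- 1 - q$gap[rt]
      free <- freep && (icons == 0L || icons == p$ncols)
      if (!free) total <- total - (if (prev == "Y") ge else go) * w
      prev <- "Y"; jcons <- jcons + 1L
    }
  }
  total
}

# exhaustive enumeration of every monotone column trace between two small
# profiles, scored directly with score_trace_oracle
oracle_profile_score <- function(p, q, scheme, terminal_free = "none") {
  L <- p$ncols; R <- q$ncols
  best <- -Inf
  path <- matrix(0L, L + R, 2L)
  rec <- function(i, j, k) {
    if (i == L && j == R) {
      s <- score_trace_oracle(path[seq_len(k - 1L), , drop = FALSE],
                              p, q, scheme, terminal_free)
      if (s > best) best <<- s
      return(invisible(NULL))
    }
    if (i < L && j < R) {
      path[k, ] <<- c(i + 1L, j + 1L); rec(i + 1L, j + 1L, k + 1L)
    }
    if (i < L) { path[k, ] <<- c(i + 1L, 0L); rec(i + 1L, j, k + 1L) }
    if (j < R) { path[k, ] <<- c(0L, j + 1L); rec(i, j + 1L, k + 1L) }
  }
  rec(0L, 0L, 1L)
  best
}

# quadratic residue-pair enumeration of the sum-of-pairs accuracy
oracle_accuracy <- function(estimated, true, focus = NULL) {
  if (is.null(focus)) focus <- true$ids
  tm <- aln_matrix(true)
  em <- aln_matrix(estimated)[match(true$ids, estimated$ids), , drop = FALSE]
  ids <- true$ids
  aligned_pairs <- function(m, i, j) {
    # set of (ordinal_i, ordinal_j) residue pairs sharing a column
    oi <- cumsum(m[i, ] != "-"); oj <- cumsum(m[j, ] != "-")
    both <- which(m[i, ] != "-" & m[j, ] != "-")
    if (length(both) == 0L) return(character(0L))
    paste(oi[both], oj[both])
  }
  accs <- numeric(0L)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      if (!(ids[i] %in% focus) && !(ids[j] %in% focus)) next
      tp <- aligned_pairs(tm, i, j)
      if (length(tp) == 0L) next
      ep <- aligned_pairs(em, i, j)
      accs <- c(accs, sum(tp %in% ep) / length(tp))
    }
  }
  mean(accs)
}

random_seq <- function(len) paste(sample(NT4, len, replace = TRUE),
                                  collapse = "")

# random gapped alignment block with the given shape (never an all-gap row)
random_block <- function(nrow, ncol, gap_p = 0.2, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow))
  ids <- ids[seq_len(nrow)]
  rows <- vapply(seq_len(nrow), function(i) {
    repeat {
      ch <- sample(c(NT4, "-"), ncol, replace = TRUE,
                   prob = c(rep((1 - gap_p) / 4, 4L), gap_p))
      if (any(ch != "-") || ncol == 0L) break
    }
    paste(ch, collapse = "")
  }, "")
  alignment(ids, rows)
}

# random ultrametric tree: returns the pairwise distance matrix and the set
# of clades (sorted leaf-index sets) of the generating topology
random_ultrametric <- function(k) {
  members <- as.list(seq_len(k))
  heights <- rep(0, k)
  clades <- list()
  D <- matrix(0, k, k)
  h <- 0
  while (length(members) > 1L) {
    h <- h + runif(1L, 0.02, 0.2)
    pick <- sample.int(length(members), 2L)
    a <- members[[pick[1L]]]; b <- members[[pick[2L]]]
    D[a, b] <- 2 * h; D[b, a] <- 2 * h
    merged <- sort(c(a, b))
    clades[[length(clades) + 1L]] <- merged
    members <- c(members[-pick], list(merged))
  }
  list(D = D, clades = clades)
}

tree_clades <- function(node) {
  if (is_gt_leaf(node)) return(list())
  c(list(sort(node$leaves)),
    tree_clades(node$children[[1L]]), tree_clades(node$children[[2L]]))
}

same_clades <- function(a, b) {
  key <- function(x) paste(x, collapse = ",")
  setequal(vapply(a, key, ""), vapply(b, key, ""))
}

# place an ungapped sequence into the gap pattern of a template row (the
# sequence must have exactly as many residues as the template)
expand_to_pattern <- function(seq, template_row) {
  tpl <- strsplit(template_row, "")[[1L]]
  res <- strsplit(seq, "")[[1L]]
  stopifnot(sum(tpl != "-") == length(res))
  tpl[tpl != "-"] <- res
  paste(tpl, collapse = "")
}

# backbone-preservation check shared by several tests
preserves_backbone <- function(result, existing) {
  idx <- match(existing$ids, result$ids)
  sub <- alignment(result$ids[idx], result$rows[idx])
  identical(drop_allgap_columns(sub)$rows, existing$rows)
}

nuc_scheme <- scoring_scheme("nucleotide")
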