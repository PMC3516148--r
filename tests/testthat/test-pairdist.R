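test_that("shared 6-mer counting uses multiset-min intersection", {
  s <- "ACGTACGTAC"
  expect_equal(shared_6mer_count(s, s), 5L)
  expect_equal(shared_6mer_count("AAAAAA", "CCCCCC"), 0L)
  expect_equal(shared_6mer_count("ACGTA", "ACGTA"), 0L)  # shorter than 6

  # brute-force multiset intersection on a designed pair
  a <- "ACGTACGTACGT"; b <- "ACGTACAT"
  brute <- function(a, b) {
    ka <- substring(a, 1:(nchar(a) - 5L), 6:nchar(a))
    kb <- substring(b, 1:(nchar(b) - 5L), 6:nchar(b))
    sum(vapply(unique(ka), function(w)
      min(sum(ka == w), sum(kb == w)), 0))
  }
  expect_equal(shared_6mer_count(a, b), brute(a, b))
  expect_equal(shared_6mer_count(a, b), 1L)

  # and on random pairs
  set.seed(21)
  for (k in 1:25) {
    a <- random_seq(sample(4:20, 1L)); b <- random_seq(sample(4:20, 1L))
    expect_equal(shared_6mer_count(a, b), brute2 <- if (nchar(a) < 6L ||
      nchar(b) < 6L) 0L else brute(a, b))
  }

  # 6-mers containing wildcards are skipped
  expect_equal(shared_6mer_count("ACGTAN", "ACGTAN"), 0L)
})

test_that("sixmer_distance maps shared counts to [0,1]", {
  expect_equal(sixmer_distance("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(sixmer_distance("AAAAAA", "CCCCCC"), 1)
  expect_equal(sixmer_distance("ACGTACGTACGT", "ACGTACAT"), 1 - 1 / 3,
               tolerance = 1e-12)
  expect_equal(sixmer_distance("ACG", "ACGTACGT"), 1)  # no 6-mers in a
  # substring with contained 6-mer multiset => distance 0
  a <- "ACGGTTACGCAATG"
  b <- substr(a, 3L, 11L)
  expect_equal(sixmer_distance(a, b), 0)
})

test_that("smith_waterman agrees with the exhaustive substring-pair oracle", {
  expect_equal(smith_waterman("ACGTACGT", "ACGTACGT")$score,
               8 * nuc_scheme$match)
  h0 <- smith_waterman("AAAA", "CCCC")
  expect_equal(h0$score, 0)
  expect_equal(diff(h0$a_range), 0L)
  expect_equal(diff(h0$b_range), 0L)
  expect_equal(smith_waterman("ACGTT", "CGT")$score, 3 * nuc_scheme$match)

  set.seed(42)
  n_checked <- 0L
  while (n_checked < 200L) {
    a <- random_seq(sample(2:8, 1L))
    b <- random_seq(sample(2:8, 1L))
    hit <- smith_waterman(a, b, nuc_scheme)
    expect_equal(hit$score, oracle_local_score(a, b, nuc_scheme),
                 info = paste(a, b))
    if (hit$score > 0) {
      expect_gt(diff(hit$a_range), 0L)
      expect_gt(diff(hit$b_range), 0L)
    }
    n_checked <- n_checked + 1L
  }
})

test_that("smith_waterman matches Biostrings::pairwiseAlignment scores", {
  mat <- nuc_scheme$submat[1:4, 1:4]
  set.seed(7)
  for (k in 1:25) {
    a <- random_seq(sample(10:30, 1L))
    b <- random_seq(sample(10:30, 1L))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = nuc_scheme$gap_open - nuc_scheme$gap_extend,
      gapExtension = nuc_scheme$gap_extend, scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b, nuc_scheme)$score, max(ref, 0))
  }
})

test_that("dp_distance satisfies the distance contracts", {
  s <- "ACGTTGCA"
  expect_equal(dp_distance(s, s), 0)
  expect_equal(dp_distance("AAAA", "CCCC"), 1)   # no positive hit
  expect_equal(dp_distance("ACGTT", "CGT"), 0)   # b fully covered by a
  set.seed(5)
  for (k in 1:20) {
    a <- random_seq(sample(5:25, 1L)); b <- random_seq(sample(5:25, 1L))
    dab <- dp_distance(a, b); dba <- dp_distance(b, a)
    expect_equal(dab, dba)
    expect_gte(dab, 0); expect_lte(dab, 1)
  }
})

test_that("build_add_matrix assembles the (N+n)-square matrix per mode", {
  set.seed(9)
  existing <- setNames(vapply(1:3, function(i) random_seq(20L), ""),
                       c("e1", "e2", "e3"))
  new <- setNames(vapply(1:2, function(i) random_seq(15L), ""),
                  c("n1", "n2"))
  for (mode in c("6mer", "dp")) {
    d <- build_add_matrix(existing, new, mode = mode, scheme = nuc_scheme)
    expect_equal(dim(d), c(5L, 5L))
    expect_equal(rownames(d), c(names(existing), names(new)))
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
  }
  # n = 0 degenerates to the backbone-only matrix
  d0 <- build_add_matrix(existing, character(0L), mode = "6mer",
                         scheme = nuc_scheme)
  expect_equal(dim(d0), c(3L, 3L))
  # 6mer mode equals elementwise sixmer_distance
  d6 <- build_add_matrix(existing, new, mode = "6mer", scheme = nuc_scheme)
  all_seqs <- c(existing, new)
  for (i in 1:4) for (j in (i + 1L):5L)
    expect_equal(d6[i, j], sixmer_distance(all_seqs[[i]], all_seqs[[j]]))
  expect_error(build_add_matrix(existing, new, mode = "nope"))
})

test_that("build_addfrag_distances computes backbone and cross distances only", {
  set.seed(13)
  existing <- setNames(vapply(1:4, function(i) random_seq(40L), ""),
                       paste0("e", 1:4))
  frag <- substr(existing[["e2"]], 10L, 29L)
  new <- c(f1 = frag, f2 = "AAAAAAAAAA")
  dd <- build_addfrag_distances(existing, new, scheme = nuc_scheme)
  expect_equal(dim(dd$backbone), c(4L, 4L))
  expect_equal(dim(dd$cross), c(4L, 2L))
  # fragment identical to a substring of e2 -> distance 0 to e2
  expect_equal(dd$cross["e2", "f1"], 0)
  # dp mode backbone matches dp_distance recomputation
  expect_equal(dd$backbone["e1", "e3"],
               dp_distance(existing[["e1"]], existing[["e3"]], nuc_scheme))
  expect_true(all(dd$cross >= 0 & dd$cross <= 1))
  # single fragment -> single column
  d1 <- build_addfrag_distances(existing, new[1L], scheme = nuc_scheme)
  expect_equal(dim(d1$cross), c(4L, 1L))
})

test_that("a hopeless fragment gets distance exactly 1 to every backbone row", {
  existing <- c(e1 = "ACGTACGTACGTACGT", e2 = "ACGTACGAACGTACGT")
  # all-N fragment: wildcard scores are 0, so no positive local hit exists
  dd <- build_addfrag_distances(existing, c(fx = "NNNNNNNN"),
                                scheme = nuc_scheme)
  expect_true(all(dd$cross[, "fx"] == 1))
})
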