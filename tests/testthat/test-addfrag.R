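frag_bb <- alignment(c("e1", "e2"),
                     c("ACGTACCGGATCGATT", "ACGTACCGGATCGATT"))
frag_dd <- build_addfrag_distances(degap(frag_bb),
                                   c(f = "GTACCG"), scheme = nuc_scheme)

test_that("a fragment equal to a backbone block is placed without insertions", {
  pf <- place_fragment(frag_bb, frag_dd$backbone, c(f = "GTACCG"),
                       frag_dd$cross[, 1L], nuc_scheme)
  expect_s3_class(pf, "placed_fragment")
  expect_equal(pf$row, "--GTACCG--------")
  expect_length(pf$insertions, 0L)
  expect_false(pf$unplaceable)
})

test_that("extra residues inside a fragment become one anchored insertion", {
  frag <- c(f = "GTACCGTTGATC")  # backbone cols 3..12 with TT inserted after col 8
  dd <- build_addfrag_distances(degap(frag_bb), frag, scheme = nuc_scheme)
  pf <- place_fragment(frag_bb, dd$backbone, frag, dd$cross[, 1L],
                       nuc_scheme)
  expect_equal(pf$row, "--GTACCGGATC----")
  expect_length(pf$insertions, 1L)
  expect_equal(pf$insertions[[1L]]$anchor, 8L)
  expect_equal(pf$insertions[[1L]]$segment, "TT")
})

test_that("a fragment with no similarity falls back to the full profile", {
  frag <- c(fx = "NNNNNNNN")
  dd <- build_addfrag_distances(degap(frag_bb), frag, scheme = nuc_scheme)
  expect_message(
    pf <- place_fragment(frag_bb, dd$backbone, frag, dd$cross[, 1L],
                         nuc_scheme),
    "no similarity")
  expect_true(pf$unplaceable)
  out <- suppressMessages(add_fragments(frag_bb, frag, nuc_scheme))
  expect_equal(attr(out, "unplaceable"), "fx")
  expect_identical(unname(degap(out)["fx"]), "NNNNNNNN")
})

test_that("merge_placements inserts corresponding gaps across all rows", {
  bb <- alignment(c("a", "b"), c("ACGT", "ACGT"))
  f1 <- placed_fragment("f1", "ACGT",
                        list(list(anchor = 2L, segment = "AA")))
  f2 <- placed_fragment("f2", "--GT")
  out <- merge_placements(bb, list(f1, f2), nuc_scheme)
  expect_equal(out$ncols, 6L)
  expect_equal(out$ids, c("a", "b", "f1", "f2"))
  expect_equal(out$rows, c("AC--GT", "AC--GT", "ACAAGT", "----GT"))

  # no insertions anywhere -> no new columns
  out0 <- merge_placements(bb, list(placed_fragment("g1", "AC--"),
                                    placed_fragment("g2", "--GT")))
  expect_equal(out0$ncols, 4L)
  expect_equal(out0$rows[3:4], c("AC--", "--GT"))

  # same-anchor single-letter insertions share one column
  h1 <- placed_fragment("h1", "ACGT", list(list(anchor = 2L, segment = "A")))
  h2 <- placed_fragment("h2", "ACGT", list(list(anchor = 2L, segment = "A")))
  out1 <- merge_placements(bb, list(h1, h2), nuc_scheme)
  expect_equal(out1$ncols, 5L)
  expect_equal(out1$rows, c("AC-GT", "AC-GT", "ACAGT", "ACAGT"))

  expect_error(merge_placements(bb, list(placed_fragment(
    "z", "ACGT", list(list(anchor = 9L, segment = "A"))))), "anchor")
})

test_that("disjoint windows of a backbone row map onto that row's columns", {
  set.seed(91)
  base <- random_seq(60L)
  mut <- function(s, k) {
    res <- strsplit(s, "")[[1L]]
    i <- sample(60L, k)
    res[i] <- vapply(res[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    paste(res, collapse = "")
  }
  bb <- alignment(paste0("e", 1:3), c(base, mut(base, 6L), mut(base, 6L)))
  frags <- c(w1 = substr(base, 1L, 20L), w2 = substr(base, 21L, 40L),
             w3 = substr(base, 41L, 60L))
  out <- add_fragments(bb, frags, nuc_scheme)
  expect_equal(out$ncols, bb$ncols)   # exact substrings: nothing to insert
  expect_equal(out$rows[4:6],
               c(paste0(substr(base, 1, 20), strrep("-", 40)),
                 paste0(strrep("-", 20), substr(base, 21, 40), strrep("-", 20)),
                 paste0(strrep("-", 40), substr(base, 41, 60))))
  ref <- alignment(c(bb$ids, names(frags)), c(bb$rows, out$rows[4:6]))
  expect_equal(accuracy(out, ref, focus = names(frags)), 1.0)
})

test_that("placements are independent of which other fragments are present", {
  set.seed(97)
  for (k in 1:6) {
    sim <- simulate_msa(sim_config(taxa = sample(6:10, 1L),
                                   sub_rate = runif(1L, 0.05, 0.15),
                                   indel_rate = 0.3, root_length = 70L,
                                   fragment_length = 20L,
                                   withheld = 2L, seed = 200L + k))
    if (length(sim$new) < 2L) next
    all_pl <- fragment_placements(sim$existing, sim$new, nuc_scheme)
    pick <- sample(seq_along(sim$new), 1L)
    solo <- fragment_placements(sim$existing, sim$new[pick], nuc_scheme)
    expect_identical(all_pl[[pick]], solo[[1L]])
  }
})

test_that("fragment input order only permutes rows and same-anchor blocks", {
  set.seed(103)
  sim <- simulate_msa(sim_config(taxa = 8L, sub_rate = 0.1,
                                 indel_rate = 0.35, root_length = 80L,
                                 fragment_length = 20L, withheld = 2L,
                                 seed = 301L))
  out1 <- add_fragments(sim$existing, sim$new, nuc_scheme)
  perm <- rev(seq_along(sim$new))
  out2 <- add_fragments(sim$existing, sim$new[perm], nuc_scheme)
  anchors_of <- function(existing, new) {
    pl <- fragment_placements(existing, new, nuc_scheme)
    sort(unlist(lapply(pl, function(p)
      vapply(p$insertions, function(i) i$anchor, 0L))))
  }
  expect_identical(anchors_of(sim$existing, sim$new),
                   anchors_of(sim$existing, sim$new[perm]))
  expect_true(preserves_backbone(out2, sim$existing))
  expect_identical(sort(degap(out1)), sort(degap(out2)))
})

test_that("merged output keeps original backbone columns in order", {
  set.seed(107)
  sim <- simulate_msa(sim_config(taxa = 8L, sub_rate = 0.1,
                                 indel_rate = 0.4, root_length = 70L,
                                 fragment_length = 20L, withheld = 2L,
                                 seed = 401L))
  out <- add_fragments(sim$existing, sim$new, nuc_scheme)
  expect_true(preserves_backbone(out, sim$existing))
  # the map from original to merged columns is strictly increasing: merged
  # backbone rows restricted to non-inserted columns equal the originals
  m <- aln_matrix(out)[seq_along(sim$existing$ids), , drop = FALSE]
  inserted <- colSums(m != "-") == 0L
  expect_equal(apply(m[, !inserted, drop = FALSE], 1L, paste, collapse = ""),
               sim$existing$rows)
})

test_that("add_fragments with one fragment equals place-and-merge of one", {
  frag <- c(f = "GTACCG")
  out <- add_fragments(frag_bb, frag, nuc_scheme)
  pf <- place_fragment(frag_bb, frag_dd$backbone, frag, frag_dd$cross[, 1L],
                       nuc_scheme)
  merged <- merge_placements(frag_bb, list(pf), nuc_scheme)
  expect_equal(out$rows, merged$rows)
  expect_equal(out$ids, merged$ids)
})
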