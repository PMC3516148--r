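# Synthetic benchmark: a root sequence is evolved along a random binary
# tree with per-branch substitutions and geometric-length indels while true
# column homology is tracked explicitly (every residue carries a globally
# ordered site key; a true-alignment column is the set of residues sharing
# a key). A configured subset of rows is withdrawn, optionally cut into
# non-overlapping fragments, and the remaining rows (all-gap columns
# removed) form the "existing alignment". The accuracy statistic is the
# fraction of residue pairs aligned in the true alignment that are also
# aligned in the estimated alignment, averaged over sequence pairs.

#' Configuration for the synthetic benchmark generator
#'
#' @param taxa Number of leaf sequences (>= 3).
#' @param sub_rate Per-site substitution probability per branch, in
#'   `[0, 1]`.
#' @param indel_rate Probability, per branch, of one insertion event and
#'   (independently) one deletion event, in `[0, 1]`.
#' @param indel_len_p Geometric success parameter for indel lengths
#'   (length = 1 + Geom(p); mean `1/p`).
#' @param root_length Number of residues in the root sequence.
#' @param fragment_length `"full"` to withdraw whole sequences, or a window
#'   length: each withheld sequence is cut into consecutive non-overlapping
#'   windows of this length (a trailing remainder shorter than the window is
#'   discarded).
#' @param withheld Number of rows to withdraw and re-add (`< taxa`).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(taxa = 20L, sub_rate = 0.05, indel_rate = 0.2,
                       indel_len_p = 0.4, root_length = 100L,
                       fragment_length = "full", withheld = 4L, seed = 1L) {
  stopifnot(taxa >= 3L, root_length >= 10L,
            sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            indel_len_p > 0, indel_len_p <= 1,
            withheld >= 1L, withheld < taxa)
  if (!identical(fragment_length, "full")) {
    fragment_length <- as.integer(fragment_length)
    stopifnot(fragment_length >= 6L)
  }
  structure(list(taxa = as.integer(taxa), sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_len_p = indel_len_p,
                 root_length = as.integer(root_length),
                 fragment_length = fragment_length,
                 withheld = as.integer(withheld), seed = as.integer(seed)),
            class = "sim_config")
}

NT <- c("A", "C", "G", "T")

# one branch of evolution over (keys, residues); st holds the global site
# key order and the next free key
evolve_branch <- function(keys, res, cfg, st) {
  L <- length(res)
  hit <- runif(L) < cfg$sub_rate
  if (any(hit)) {
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    res[hit] <- NT[((match(res[hit], NT) - 1L + shift) %% 4L) + 1L]
  }
  if (length(res) > 1L && runif(1) < cfg$indel_rate) {  # deletion
    len <- min(rgeom(1L, cfg$indel_len_p) + 1L, length(res) - 1L)
    start <- sample.int(length(res) - len + 1L, 1L)
    drop <- start:(start + len - 1L)
    keys <- keys[-drop]; res <- res[-drop]
  }
  if (runif(1) < cfg$indel_rate) {                      # insertion
    len <- rgeom(1L, cfg$indel_len_p) + 1L
    pos <- sample.int(length(res) + 1L, 1L) - 1L        # insert after pos
    newres <- sample(NT, len, replace = TRUE)
    newkeys <- st$nextkey + seq_len(len) - 1L
    st$nextkey <- st$nextkey + len
    after <- if (pos == 0L) match(keys[1L], st$keyorder) - 1L
             else match(keys[pos], st$keyorder)
    st$keyorder <- append(st$keyorder, newkeys, after = after)
    keys <- append(keys, newkeys, after = pos)
    res <- append(res, newres, after = pos)
  }
  list(keys = keys, res = res)
}

random_join_tree <- function(k) {
  nodes <- lapply(seq_len(k), new_gt_leaf)
  h <- 0
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    h <- h + 0.05
    merged <- new_gt_node(nodes[[pick[1L]]], nodes[[pick[2L]]], h)
    nodes <- c(nodes[-pick], list(merged))
  }
  structure(nodes[[1L]], class = "guide_tree", nleaves = k,
            labels = paste0("t", seq_len(k)))
}

#' Simulate a benchmark instance with known true homology
#'
#' Evolves a random root sequence along a random binary tree with
#' substitutions and indels, tracking true column homology, then withdraws
#' the configured number of rows. The remaining rows with all-gap columns
#' removed form the existing alignment; the withdrawn rows (degapped, and
#' optionally cut into non-overlapping fragments) are the sequences to be
#' re-added. The returned `reference` alignment holds the true columns of
#' the backbone rows together with one row per new sequence (fragments
#' occupy the columns of their source window) and is the ground truth that
#' [accuracy()] scores against.
#'
#' @param cfg A [sim_config()].
#' @return A list with `true` (full true `msa`), `existing` (`msa`), `new`
#'   (named character vector), `reference` (`msa` over backbone + new ids),
#'   `tree` (the generating `guide_tree`) and `withheld_ids`.
#' @export
simulate_msa <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    st <- new.env(parent = emptyenv())
    st$keyorder <- seq_len(cfg$root_length)
    st$nextkey <- cfg$root_length + 1L
    root <- list(keys = seq_len(cfg$root_length),
                 res = sample(NT, cfg$root_length, replace = TRUE))
    tree <- random_join_tree(cfg$taxa)
    leaves <- vector("list", cfg$taxa)
    descend <- function(node, seqstate) {
      seqstate <- evolve_branch(seqstate$keys, seqstate$res, cfg, st)
      if (is_gt_leaf(node)) {
        leaves[[node$leaf]] <<- seqstate
        return(invisible(NULL))
      }
      descend(node$children[[1L]], seqstate)
      descend(node$children[[2L]], seqstate)
    }
    descend(tree, root)

    present <- sort(match(unique(unlist(lapply(leaves, `[[`, "keys"))),
                          st$keyorder))
    colkeys <- st$keyorder[present]
    ids <- paste0("t", seq_len(cfg$taxa))
    rows <- vapply(leaves, function(lf) {
      r <- rep("-", length(colkeys))
      r[match(lf$keys, colkeys)] <- lf$res
      paste(r, collapse = "")
    }, "")
    true <- alignment(ids, rows)

    wh <- sort(sample.int(cfg$taxa, cfg$withheld))
    keep <- setdiff(seq_len(cfg$taxa), wh)
    existing <- drop_allgap_columns(alignment(ids[keep], rows[keep]))

    withheld_seqs <- degap(alignment(ids[wh], rows[wh]))
    tm <- aln_matrix(true)
    new <- character(0L)
    refrows <- list()
    if (identical(cfg$fragment_length, "full")) {
      new <- withheld_seqs
      for (i in seq_along(wh)) refrows[[ids[wh[i]]]] <- rows[wh[i]]
    } else {
      flen <- cfg$fragment_length
      if (flen > min(nchar(withheld_seqs)))
        stop("fragment length ", flen, " exceeds the shortest withheld ",
             "sequence (", min(nchar(withheld_seqs)), " residues)")
      for (i in seq_along(wh)) {
        s <- withheld_seqs[i]
        id <- ids[wh[i]]
        nres <- nchar(s)
        rescols <- which(tm[wh[i], ] != "-")   # true column of each residue
        nwin <- nres %/% flen
        for (k in seq_len(nwin)) {
          from <- (k - 1L) * flen + 1L
          to <- k * flen
          fid <- paste0(id, "_f", k)
          new[fid] <- substr(s, from, to)
          r <- rep("-", true$ncols)
          r[rescols[from:to]] <- tm[wh[i], rescols[from:to]]
          refrows[[fid]] <- paste(r, collapse = "")
        }
      }
    }
    reference <- drop_allgap_columns(
      alignment(c(ids[keep], names(refrows)),
                c(rows[keep], unlist(refrows, use.names = FALSE))))
    list(true = true, existing = existing, new = new,
         reference = reference, tree = tree, withheld_ids = ids[wh])
  })
}

# per-row vector of residue ordinals by column (0 at gaps)
residue_ordinals <- function(a) {
  m <- aln_matrix(a)
  ng <- m != "-"
  ords <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) ords[i, ng[i, ]] <- seq_len(sum(ng[i, ]))
  rownames(ords) <- a$ids
  ords
}

#' Sum-of-pairs alignment accuracy against a true alignment
#'
#' For every unordered sequence pair with at least one id in `focus`, counts
#' the residue-residue pairs that share a column in the true alignment and
#' also share a column in the estimated alignment; the pair's accuracy is
#' this count divided by the number of aligned letter pairs in the true
#' alignment. Pairs with no aligned letters in the truth are skipped. The
#' unweighted mean over pairs is returned.
#'
#' @param estimated,true `msa` objects with identical ids and identical
#'   ungapped row content.
#' @param focus Ids defining the pair set (default: all ids, i.e. every
#'   pair). Typically the added sequences, since backbone-backbone pairs
#'   are fixed by construction.
#' @return A fraction in `[0, 1]` (`NaN` if no pair has aligned letters in
#'   the truth).
#' @export
accuracy <- function(estimated, true, focus = NULL) {
  stopifnot(inherits(estimated, "msa"), inherits(true, "msa"))
  if (!setequal(estimated$ids, true$ids))
    stop("estimated and true alignments contain different ids")
  ord <- match(true$ids, estimated$ids)
  if (!identical(degap(true$rows), degap(estimated$rows[ord])))
    stop("estimated and true alignments disagree on ungapped row content")
  if (is.null(focus)) focus <- true$ids
  if (!all(focus %in% true$ids)) stop("focus ids not present")
  ids <- true$ids
  ot <- residue_ordinals(true)
  oe <- residue_ordinals(estimated)[ord, , drop = FALSE]
  base <- max(nchar(degap(true$rows))) + 1L
  pairkeys <- function(ords, i, j) {
    both <- ords[i, ] > 0L & ords[j, ] > 0L
    as.numeric(ords[i, both]) * base + ords[j, both]
  }
  accs <- numeric(0L)
  infocus <- ids %in% focus
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      if (!infocus[i] && !infocus[j]) next
      tk <- pairkeys(ot, i, j)
      if (length(tk) == 0L) next
      ek <- pairkeys(oe, i, j)
      accs <- c(accs, sum(tk %in% ek) / length(tk))
    }
  }
  mean(accs)
}

#' Profile-sequence baseline
#'
#' Aligns each new sequence separately against the profile of the entire
#' existing alignment (no guide tree), then merges the independent results
#' with [merge_placements()]. This treats the existing alignment as a flat
#' profile and ignores the phylogenetic relationship between the new
#' sequences and the alignment's rows, so it serves as the baseline the
#' tree-aware methods are compared against.
#'
#' @inheritParams add_fragments
#' @return An `msa` with backbone rows first, then the new sequences.
#' @export
profile_baseline <- function(existing, new, scheme = NULL) {
  stopifnot(inherits(existing, "msa"))
  if (length(new) < 1L) stop("no new sequences")
  if (any(names(new) %in% existing$ids))
    stop("id collision with the existing alignment")
  scheme <- default_scheme(c(existing$rows, new), scheme)
  placed <- lapply(seq_along(new), function(j)
    place_against_rows(existing, existing$ids, names(new)[j],
                       unname(new[j]), scheme))
  merge_placements(existing, placed, scheme)
}

#' Run a seeded benchmark over simulated replicates
#'
#' For each replicate a fresh instance is simulated (seed `cfg$seed + r -
#' 1`), each requested method re-adds the withdrawn sequences, and the
#' result is scored with [accuracy()] against the true columns (focus = the
#' added sequences). Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param replicates Number of simulated replicates (>= 1).
#' @param methods Subset of `"addfragments"`, `"add_dp"`, `"add_6mer"`,
#'   `"profile"`.
#' @param scheme A [scoring_scheme()].
#' @return A list with `per_replicate` (data frame of replicate, method,
#'   accuracy) and `summary` (data frame of method, mean_accuracy).
#' @export
run_benchmark <- function(cfg, replicates = 20L,
                          methods = c("addfragments", "add_dp", "add_6mer",
                                      "profile"),
                          scheme = NULL) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(scheme)) scheme <- scoring_scheme("nucleotide")
  res <- list()
  for (r in seq_len(replicates)) {
    cfgr <- cfg
    cfgr$seed <- cfg$seed + r - 1L
    sim <- simulate_msa(cfgr)
    for (m in methods) {
      est <- switch(m,
        addfragments = add_fragments(sim$existing, sim$new, scheme),
        add_dp = add_sequences(sim$existing, sim$new, "dp", scheme),
        add_6mer = add_sequences(sim$existing, sim$new, "6mer", scheme),
        profile = profile_baseline(sim$existing, sim$new, scheme))
      acc <- accuracy(est, sim$reference, focus = names(sim$new))
      res[[length(res) + 1L]] <- data.frame(replicate = r, method = m,
                                            accuracy = acc)
    }
  }
  per <- do.call(rbind, res)
  summ <- stats::aggregate(accuracy ~ method, per, mean)
  names(summ)[2L] <- "mean_accuracy"
  list(per_replicate = per, summary = summ[match(methods, summ$method), ,
                                           drop = FALSE])
}
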