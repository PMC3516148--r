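---
title: "Adding sequences and fragments into an existing alignment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adding sequences and fragments into an existing alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnadd)
```

## The problem

Curated multiple sequence alignments (MSAs) encode biological knowledge in
their column structure: each column is a hypothesis of homology. When new
sequences arrive — newly determined genes, or short sequencing reads — it is
usually better to *add* them to the trusted alignment than to realign
everything from scratch, both for speed and because realignment would
discard the curation. The constraint that makes this non-trivial is that
the existing columns must not move: the only permitted edit to the backbone
is the insertion of full gap columns.

`alnadd` implements two strategies for this, plus the machinery to evaluate
them.

## Strategy 1: guide-tree-constrained progressive addition (`add_sequences`)

For $N$ backbone sequences and $n$ full-length new sequences:

1. Compute an $(N+n) \times (N+n)$ distance matrix over all sequences
   (backbone rows are degapped first). Two distance modes are available:
   shared 6-mer counts (fast, alignment-free) or Smith–Waterman local
   alignment scores. Either similarity $S$ is converted to a distance
   $d = 1 - S / \min(S_{aa}, S_{bb})$, clamped to $[0,1]$, where $S_{aa}$
   is the self-similarity; identical sequences get $d = 0$ and pairs with
   no similarity get $d = 1$.
2. Build a rooted guide tree with $N+n$ tips by UPGMA.
3. Traverse the tree in postorder. Nodes whose leaves are all in the
   backbone (or already merged into its coordinate system) need no
   computation — the backbone is frozen. When a subtree of new sequences
   meets the backbone, its sub-alignment is aligned against the profile of
   the backbone subtree's rows, taken over the *full* current column set;
   any gap opened on the backbone side becomes a full gap column across
   every row. Two all-new subtrees are merged by ordinary profile–profile
   alignment.

Removing the new rows and dropping all-gap columns always reproduces the
input alignment exactly; this invariant is enforced by construction and
checked extensively in the test suite.

This strategy assumes the new sequences are comparable over their whole
length. When they are non-overlapping fragments, the fragment–fragment
entries of the distance matrix are mostly meaningless (non-homologous
fragments are forced into alignment), the guide tree groups fragments into
spurious clades, and quality collapses — the benchmark below demonstrates
this.

## Strategy 2: independent fragment placement (`add_fragments`)

Short reads rarely overlap each other, so no relationship among them is
assumed:

1. Compute the $N \times N$ backbone distance matrix (Smith–Waterman
   based).
2. Compute $N \times n$ local alignments between backbone sequences and
   fragments; only the best hit per pair is used. A pair with no
   positive-scoring local alignment gets distance exactly 1.
3. For each fragment independently: build an $(N+1)$-tip UPGMA tree from
   the backbone matrix plus that fragment's cross distances; take the
   fragment's sibling subtree in that tree as its attachment point; align
   the fragment against the profile of those rows over the full column
   set, with free terminal gaps on the fragment side. The result is
   reduced to a row over the original columns plus *insertion records*
   (segment, anchored at an inter-column position).
4. Merge the $n$ placements: where one fragment inserted a segment, a
   corresponding gap block is inserted into the backbone and all other
   fragments; where several fragments insert at the same anchor, their
   segments are aligned to each other and the joint block is inserted
   once.

Because step 3 depends only on (backbone, backbone distances, one
fragment), placements are pure per-fragment functions: placing a fragment
alone or with any other fragments yields the identical record. This is
tested directly, and is the contract a parallel implementation would rely
on. The reference implementation is sequential.

A fragment whose cross distances are all 1 cannot be attached by
similarity. It is not dropped: it is aligned against the full-alignment
profile, flagged in the returned `unplaceable` attribute and reported on
stderr.

## The alignment engine

Every progressive step runs the same primitive: affine-gap global DP over
two profiles. Design choices:

* **Column score.** Expected pairwise substitution score
  $\sum_{x,y} f_p(x) f_q(y) s(x,y)$ over residue frequencies; gap
  fractions do not enter the substitution term. Rows are weighted
  uniformly (no MAFFT-style sequence weighting — a deliberate
  simplification).
* **Gap costs.** A gap of length $k$ costs
  $g_{open} + (k-1)\, g_{ext}$, each term scaled by
  $(1 - \text{gap fraction})$ of the column it is placed against, so
  gapping against an already-sparse column is cheap. This prevents
  over-penalising the sparse columns that fragment blocks produce.
* **Terminal gap policy.** Fragments must not pay for the flanks they do
  not cover, so fragment placement uses free terminal gaps on the fragment
  side (`q_side`); full-length addition penalises all gaps (`none`).
* **Determinism.** All tie-breaking is fixed: the DP prefers a column
  match, then a gap in the right profile, then a gap in the left, applied
  identically in the forward pass and traceback; Smith–Waterman ties on
  the optimal score resolve to the smallest end coordinate; UPGMA ties on
  the minimum pair distance resolve to the lexicographically smallest
  cluster labels (label = smallest original index). Identical inputs give
  byte-identical outputs.
* **Scoring defaults.** Nucleotide: match $+2$, mismatch $-1$,
  $g_{open} = 4$, $g_{ext} = 1$; `N` and IUPAC ambiguity codes score 0
  against everything. Protein: BLOSUM62 with $g_{open} = 11$,
  $g_{ext} = 1$; `X` is the wildcard. These are conventional values — the
  method does not prescribe a parameter set — and all are configurable
  through `scoring_scheme()`. The similarity-to-distance transform above
  is likewise a documented choice satisfying the required range and
  boundary behaviour; no correction terms are applied. Reverse-complement
  handling is deliberately absent: inputs are assumed correctly oriented.

Same-anchor insert blocks are aligned progressively in fragment input
order. Longest-first joining was considered and rejected: input order is
simpler and equally deterministic, and the blocks involved are typically
one or two residues.

## The synthetic benchmark

There is no established real-data benchmark for alignment extension, so
evaluation uses simulation with known homology. `simulate_msa()` evolves a
random root sequence along a random binary join tree. Per branch, every
site substitutes with probability `sub_rate` (uniform choice among the
three other bases); one insertion and one deletion each occur with
probability `indel_rate`, with lengths $1 + \mathrm{Geom}(p)$ at uniform
positions. Every residue carries a globally ordered site key, so true
column homology is exact by construction, not inferred. A configured
number of rows is withdrawn; the rest (all-gap columns dropped) form the
existing alignment; the withdrawn rows are returned whole or cut into
consecutive non-overlapping windows (a trailing remainder shorter than
one window is discarded).

`accuracy()` implements the standard sum-of-pairs score: the fraction of
residue pairs aligned in the true alignment that are also aligned in the
estimate, averaged over sequence pairs. By default only pairs involving at
least one added sequence are counted, since backbone–backbone pairs are
fixed by construction; the pair set is configurable via `focus`.

What the simulator does *not* emulate: rate heterogeneity across sites and
lineages, sequencing error, compositional bias, repeats and domain
shuffling, and realistic indel length spectra. Passing tests on this
generator demonstrate the algorithmic contracts (preservation,
independence, exact recovery, the ranking of methods under divergence) —
not field performance on any particular real dataset.

### Study conditions

The packaged evaluation (`scripts/acceptance.R`, and the corresponding
tests) uses these problem sizes, chosen once as a desk-scale stand-in for
a "moderately hard, short fragments" regime:

* benchmark: 24 taxa, 5 withdrawn, root length 120, per-branch
  substitution rate 0.12, indel rate 0.3 (mean length $\approx 2.9$),
  fragment windows of 25 nt, 20 replicates;
* exact-recovery check: 15 taxa, 3 withdrawn, substitution rate 0.05,
  indel rate 0 (so added material is an exact substring of a withheld
  row and perfect recovery is achievable and required);
* preservation sweep: 100 fixtures with 10–50 backbone rows, 1–20 added
  sequences or fragments, substitution rates 0.02–0.25 and indel rates
  0.1–0.5.

Under the benchmark condition the tree-aware fragment placement clearly
outperforms the flat profile baseline, and the progressive `add` strategy
collapses when its input is fragmented but performs well on the
full-length versions of the same sequences — the two contrasts that
motivate having two strategies at all. The exact numbers for the current
build are computed, not quoted, by:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Numerical and degenerate-input choices

* Distances are clamped to $[0,1]$ after the transform; a zero
  self-similarity (possible only for all-wildcard sequences) maps to
  distance 1.
* UPGMA requires at least two items; heights are clamped to be
  non-decreasing toward the root to absorb floating-point noise in the
  average-linkage update (average linkage is monotone in exact
  arithmetic).
* A 0-column alignment is representable (e.g. after dropping all columns
  of an all-gap row) but cannot be written to FASTA or profiled.
* 6-mers containing a wildcard are skipped in counting; sequences shorter
  than 6 residues have no 6-mers and get 6-mer distance 1 to everything.
* Empty insertion segments and out-of-range anchors are rejected at the
  merge boundary.

## Known limitations

* $O((N+n)^2)$ distances for `add_sequences` and $O(N^2)$ for
  `add_fragments` in time and memory; no sparse or seed-based
  acceleration hook is implemented beyond the pluggable scoring scheme.
* No sequence weighting in profiles; very unbalanced backbones will bias
  profile columns toward over-represented clades.
* One strand only; no reverse-complement search.
* The progressive order within a batch matters: adding sequences one at a
  time and all at once may differ (each result still preserves the
  backbone).
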