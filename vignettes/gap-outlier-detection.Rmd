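---
title: "Gap-based outlier detection in multiple sequence alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-based outlier detection in multiple sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaoutlier)
```

## The model

An outlier in a multiple sequence alignment — a non-homologous
interloper, a mistranslated stretch, a barely alignable distant relative
— misaligns against the rest of the family, and the aligner expresses
that misalignment as gaps: the sequence opens gaps where the family has
residues and vice versa. This package therefore scores sequences purely
by gap placement. Residue identity never enters the computation, which
is what makes the method cheap enough for alignments of hundreds of
thousands of rows, and is also its central assumption: **a sequence is
anomalous if and only if its gap pattern is anomalous.** Alignments
produced under very heavy gap penalties carry little gap signal and the
method loses power there; an alignment whose gap patterns are all
identical is reported as "no gap signal" rather than scored.

Each sequence is recoded as a binary mask over the $L$ alignment
columns, $X_{i,l} = 1$ at a gap. For a pair $(i, j)$, columns where the
masks disagree contribute to the distance $S_{i,j}$ under one of three
metrics:

* **linear**: each disagreeing column scores 1. This is the Hamming
  distance between masks; it is blind to how disagreements group into
  runs, satisfies the triangle inequality, and is the default.
* **affine**: a disagreeing column scores 3 when the previous column
  agreed (a mismatch run opens) and 1 when it extends. Column 1 has no
  predecessor; a disagreement there is scored as an opening — the only
  self-consistent reading of an opening/extension scheme at the
  boundary. Many short gaps weigh more than one long gap:
  $\mathrm{linear} \le \mathrm{affine} \le 3\,\mathrm{linear}$.
* **cumulative**: the per-column score is 0 on agreement and otherwise
  one more than the previous column's score (taken as 0 before the first
  column), so a run of $k$ disagreeing columns contributes
  $k(k+1)/2$ and long gaps dominate. It equals the linear metric
  whenever no two adjacent columns both disagree.

All three depend only on the per-column agreement sequence and are
therefore symmetric. The per-sequence raw score is the **mean** distance
to the other $N-1$ sequences. Using the mean rather than the sum keeps
scores commensurable between the full and seed modes and across $N$;
both normalisations below are scale-invariant, so this choice cannot
change any classification.

### Seed approximation for large alignments

The full matrix costs $N(N-1)/2$ pair evaluations. For large $N$ the
package instead computes distances from $M$ seed sequences drawn
uniformly without replacement (at most $MN$ evaluations) and scores each
sequence by its mean distance to the seeds. The default
$M = \max(5, \lceil \log_2 N \rceil)$ follows the embedding heuristic
used in large-scale guide-tree construction; the floor of 5 keeps small
inputs stable, and $M$ is user-settable. A seed's zero self-distance is
excluded from its own mean (dividing by $M-1$), otherwise every seed
would be biased toward the core. With $M = N$ the seed mode reproduces
the full-mode means exactly, which the tests pin.

The approximation is reliable when the mean distance is dominated by a
sequence's own gap content. That is a real constraint, not a technical
one: writing $g_i$ for sequence $i$'s gap count and $o_{ij}$ for the
shared gap columns, the linear distance is
$S_{ij} = g_i + g_j - 2 o_{ij}$. In a family whose optional gap blocks
are present with probability $p$, the expected overlap against a random
partner is $\approx p\, g_i$, so the mean distance scales like
$(1 - 2p) g_i + \mathrm{const}$. At $p \approx 0.5$ the sequence's own
contribution cancels and *no* estimator of the mean — including the full
matrix — carries gap-content signal; rank agreement between seed and
full modes is then meaningless noise. The package's fidelity checks
therefore use the fragment-rich, sparse-gap family composition described
below, which is also the regime (large full alignments with many partial
sequences) the approximation exists for.

### Normalisation and classification

Raw mean distances are not comparable across datasets, so they are
normalised before thresholding, in one of two ways:

* **Bootstrap** (default): $B$ pseudo-replicates of size $N$ are drawn
  with replacement from the raw scores; $\bar{s}$ is the mean of the
  replicate means and $\sigma$ the mean of the replicate sample standard
  deviations (divisor $N-1$). The outlier score is the signed
  $z$-like quantity $(D_i - \bar{s})/\sigma$. $B = 1000$ by default —
  replicate-mean noise is then well under a percent of $\sigma$ and the
  cost is negligible next to the distance computation.
* **Interquartile range**: $Q1$ and $Q3$ are the type-7 interpolated
  quartiles of the sorted scores (ranks $0.25(N-1)$ and $0.75(N-1)$ on
  the 0-indexed vector; the estimator is an argument, pinned in the
  tests) and $r = Q3 - Q1$. Scores strictly inside $(Q1, Q3)$ are
  exactly 0; above the box the score is $(D_i - Q3)/r$; below it the
  shortfall $(Q1 - D_i)/r$ is stored with a negative sign so one signed
  vector carries both tails.

A sequence is flagged when its score exceeds the threshold $T$ on the
active tail: `upper` (default) flags score $> T$, `lower` flags
$-\mathrm{score} > T$, `both` flags $|\mathrm{score}| > T$. The
score-exceeds-threshold rule is applied on both tails; on the lower tail
it is the magnitude of the shortfall that is compared. The default tail
is upper-only because an aberrant sequence is unusually *far* from the
rest — a sequence unusually close to everything is not an alignment
outlier. For similarity-kind scores (the unaligned mode) the sign is
flipped before the tail logic, since there an anomalously *low* total is
suspicious. $T = 2$ by default; raising $T$ only ever shrinks the
flagged set, and 2–10 spans the useful stringency range.

Two degenerate inputs are errors rather than silent all-core results:
$\sigma = 0$ (all scores identical; no finite score exists) and $r = 0$
(many identical scores, common in datasets with duplicated sequences),
the latter with the advice to use the bootstrap, whose estimates remain
finite there.

### Unaligned mode

Without an alignment there are no gap patterns, so pairwise similarity
comes from an external BLAST-compatible protein search at default
parameters, run all-vs-all against a database built from the input
itself, with tabular output requested explicitly so parsing is stable
across tool versions. The best bit score per unordered pair (maximum
over HSPs and both directions) is kept; absent hits count 0; each
sequence's raw score is its total over all pairs. Only bootstrap
normalisation is offered in this mode, and detection is less sensitive
than with an alignment — the search may simply not report the weak
similarities that distinguish a marginal homologue.

## The synthetic family generator

`family_model()` / `make_family()` simulate the evaluation design the
detector is meant for: a family sharing a gap architecture, optionally
seeded (`inject_outliers()`) with sequences of divergent architecture.
A model places non-overlapping gap blocks (nominal widths 4–12 columns)
in a column range; each block is present in each sequence with
probability `gap_prob`, with boundaries jittered by up to `jitter`
columns; with probability `frag_prob` a sequence is a fragment, its
terminus replaced by a gap run of up to `frag_max` of the length.
Fragments matter because they are the dominant gap heterogeneity of real
large family alignments, and "sequence with a large missing part" is
precisely what the metric measures. Residue columns are uniform random
amino acids: the detector never reads them, so residue realism is
irrelevant in aligned mode (unaligned-mode tests instead use mutated
copies of a master sequence, which *do* carry residue signal).

Injected outliers must have mean ungapped length within 10% of the core
mean, mirroring the practice of length-matching planted outliers so that
crude length effects do not dominate the benchmark. The benchmark
configurations used by the test suite:

* **Divergent-architecture ("different family") analog**: core blocks at
  per-block presence 0.8 in the first half of the columns; outlier
  blocks are the same widths relocated to the second half. Presence is
  high because a family's full alignment has a consensus gap structure,
  and a non-homologous sequence realigned into it reliably acquires
  divergent gaps — at low presence an injected "outlier" is often
  gap-free and indistinguishable in principle from a gap-free core
  sequence. Detection here is essentially perfect (AUC ≥ 0.95 averaged
  over 20 datasets of N = 500 with 5 outliers each).
* **Related-family analog**: outlier blocks are the family's blocks
  shifted by 2 columns — within the family's own jitter scale — so the
  architectures largely overlap. Detection degrades (AUC ≈ 0.8) but
  stays well above chance, reproducing the qualitative ordering expected
  when outliers are distant homologues rather than non-homologues.
* **False-positive rate**: 20 outlier-free families (N = 500, L = 300,
  10 blocks, presence 0.3, jitter 2); the default detector flags ≈ 3% of
  sequences at T = 2, comfortably below the 10% operating bound the
  threshold is chosen for. This is the quantity `scripts/acceptance.R`
  recomputes.
* **Seed-approximation fidelity**: the fragment-rich composition
  (10 blocks at presence 0.2, jitter 2, 20% fragments truncated up to
  30%), N = 500, M = 9; Spearman rank agreement between seed-mode and
  full-mode scores exceeds 0.9.

What the generator does **not** emulate: the composition of gaps by a
real aligner. In practice a seeded dataset would be realigned before
detection, and the aligner itself decides where the outlier's gaps land;
the generator composes masks directly. Absolute AUCs on these fixtures
are therefore not comparable to benchmarks on curated family databases —
only the qualitative ordering (divergent ≫ related ≫ none) and the
false-positive behaviour transfer. Passing tests demonstrate the
statistical machinery, not real-data sensitivity.

## Numerical and design notes

* All randomness (seed selection, bootstrap, simulation) flows through
  explicit integer seeds with the caller's RNG state restored, so every
  result in this document and in the test suite is reproducible
  bit-for-bit and repeated runs of the command-line tool are
  byte-identical.
* Distance kernels are compiled (Rcpp); the full matrix performs exactly
  $N(N-1)/2$ pair evaluations and the seed mode at most $MN$, which the
  tests assert by operation count rather than by timing.
* Mask construction is permissive: any character outside the configured
  gap set (default `-` and the Pfam-style `.`) counts as a residue, and
  comparison is case-insensitive. Duplicate ids are a hard error —
  scores are reported per id.
* Input auto-detection (leading integer → Phylip square matrix;
  equal-length gapped FASTA → alignment; otherwise unaligned) can
  misread a gap-free alignment as unaligned sequences, so the kind is
  overridable. Lower-triangular Phylip is rejected with a clear message;
  only the square dialect is read.
* Known limitations: power collapses for very small families (quartiles
  need $N \ge 4$; a handful of sequences cannot define "usual");
  sequences homologous over most of their length with one short aberrant
  region are better served by segment-level tools; nucleic-acid
  alignments are untested territory; and the pre-computed-matrix input
  cannot use the seed mode (the matrix is already complete).

## Problem sizes

The shipped tests run the full pipeline at N = 500, L = 300 (the scale
at which the full-matrix mode is still instant) with 20-dataset
averages for the stochastic properties, and verify the metric kernels
against an independent single-pass reference on 1000 random mask pairs
per metric. The seed mode has been exercised up to the tens of
thousands of sequences informally; its contract is covered at N = 500
where the full matrix is available for comparison.
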