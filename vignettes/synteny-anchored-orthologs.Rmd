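---
title: "Methods: synteny-anchored discovery of remote viral ortholog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-anchored discovery of remote viral ortholog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synortho)
```

## The problem

Some viral genes diverge so quickly that sequence similarity alone cannot
connect their most distant members: in the alphabaculoviruses (large
circular dsDNA insect viruses, split into groups I and II), the
coiled-coil gene family around *bv/odv-e26* spans homologs from ~96% down
to ~17% pairwise identity. At the low end, a direct similarity search from
any single query is unreliable. Two observations rescue the search:

1. **Synteny.** The family sits in a conserved gene neighborhood, between
   the widely conserved *egt* locus and the *Bm9* locus. Restricting the
   candidate set to the handful of ORFs between those anchors removes
   almost all of the noise a proteome-wide search would admit.
2. **Transitivity.** Homology established pairwise by reciprocal best hits
   (RBH) composes: a 17%-identity pair that no single alignment would
   accept can be connected through intermediate relatives. Taking the
   *connected component* of the RBH graph that contains a trusted seed
   gene - rather than requiring direct hits to the seed - is what lets
   remote members join.

`synortho` implements that two-step strategy as a deterministic pipeline,
plus the downstream analyses used to argue that the recovered family is
real: conservation of the coiled-coil heptad core, residue-number mapping
between divergent members, and agreement of the family tree with a
reference topology.

## Pipeline overview

For genomes $G_1, \dots, G_n$ with protein sets, reference anchor proteins
$a_{egt}, a_{Bm9}$, and a seed gene $s$:

1. **Anchoring.** In each genome, the best local-alignment hit of each
   anchor reference is accepted if its score is at least
   `min_anchor_score` (default 80) and it covers at least
   `min_anchor_coverage` (default 0.5) of the reference. Candidates are
   the genes strictly between the two anchors along the *shorter* arc of
   the circular genome; when Bm9 is absent, a symmetric window of
   `fallback_window` (default 10) genes on each side of egt is used
   instead; a genome without egt is skipped (and logged).
2. **RBH graph.** Every candidate is searched against the *full* proteome
   of every other genome by exact Smith-Waterman alignment (BLOSUM62, gap
   open 11, extend 1). An edge joins genes $g$ and $h$ iff each is the
   other's highest-scoring accepted hit (score >= `min_hit_score`,
   default 50; aligned fraction of the shorter sequence >=
   `min_hit_coverage`, default 0.25).
3. **Family.** The family is the connected component containing $s$.
   Identified anchor genes are barred from membership: they play a
   distinct role in the census (just as they are excluded from the
   candidate intervals), and without the bar a genome whose member was
   deleted and a genome whose anchor was deleted could pair their two
   widowed genes through a marginal reciprocal hit - with raw-score
   acceptance there is no significance model to reject it. If a genome
   contributes several component members, the one scoring highest against
   the seed is the member; the rest are reported as orphans. The
   presence/absence census has one row per genome (anchors, member,
   member-inside-interval flag).
4. **Coiled coil.** Members are scanned with a heptad-register scorer
   (below); their coil fragments are aligned progressively, columns are
   classified for conservation, and residue numbers can be mapped between
   members through the alignment.
5. **Tree.** A neighbor-joining tree on alignment distances
   (`1 - fraction identity`, pairwise deletion; optional Poisson
   correction) is compared to a user-supplied reference topology by
   Robinson-Foulds distance.

Every step is deterministic for fixed inputs and configuration; rerunning
the pipeline produces byte-identical files.

## Alignment engine

The scoring engine is an exact affine-gap Gotoh DP (local and global)
written in C++, not a heuristic search: the proteomes involved are tiny
(tens to a few hundred proteins), so exactness costs nothing and removes
seeding artifacts. Conventions that matter:

* A gap of length $L$ costs `gap_open` + $L \cdot$ `gap_extend` (the first
  gap residue pays both terms). Local defaults 11/1; global defaults 10/0.5.
* Traceback ties are fixed (diagonal > up > left; the local end cell is
  the maximal-scoring cell with lexicographically smallest end
  coordinates), so alignments are byte-reproducible.
* The unknown residue `X` scores 0 against everything; residues outside
  the matrix alphabet are normalized to `X`.
* Global alignments penalize terminal gaps like internal ones by default.
  An `end_gap_free = TRUE` flag provides the overlap-style convention used
  by some tools (EMBOSS Needle's web default leaves end gaps free); both
  conventions are exposed because published percent identities do not
  always state which was used.
* Percent identity is `100 * identical columns / alignment length`
  *including* gap columns, reported to one decimal - the convention under
  which the published 96.1% / 17.3% figures for the close and distant
  family pairs are defined. `X`-`X` columns do not count as identical.
* A local alignment where no residue pair scores positively is the empty
  alignment with score 0; its identity is undefined (an error, not a 0).

No E-values are computed. Acceptance is by raw score plus coverage,
exposed in `pipeline_config()`: with search spaces this small, explicit
thresholds are easier to reason about (and to test) than an extreme-value
model, at the cost that raw scores do not normalize across sequence
lengths.

## Coiled-coil scanner

A coiled coil repeats every 7 residues (letters *a*-*g*) with hydrophobic
residues at the packing core *a* and *d* (the "1st and 4th" positions of
each heptad). The scanner slides a window of `window` residues (default
21, i.e. 3 heptads; must be a multiple of 7) over the protein and, for
each of the 7 possible registers, scores the fraction of a/d positions
occupied by a residue from the hydrophobic set (default
`{I, L, V, M, F, A}`). Each window qualifies under its best register only
(ties to the smallest phase); qualifying windows of the same register are
merged into maximal intervals, and where intervals of different registers
overlap the higher-scoring one wins (the other is trimmed, and dropped if
it falls under one window). The default threshold 0.7 tolerates roughly
one non-hydrophobic core position per 3-heptad window - strict enough
that unstructured sequence rarely qualifies, loose enough that a
biological coil with an imperfect core position survives.

This is deliberately a transparent, parameter-explicit predictor rather
than a reimplementation of a PSSM-based tool: the claim it supports
downstream is only "these residues sit at heptad core positions", and
every quantity it produces can be recomputed by hand. One consequence of
maximal merging is that a perfect repeat flanked by indifferent sequence
is reported with a few flanking residues attached (any window with at
most ~30% of its core positions in the flank still qualifies), so interval
boundaries are approximately, not exactly, the underlying coil.

## Progressive alignment and conservation

Family members are aligned with a guide-tree progressive aligner: pairwise
global identities give distances, a UPGMA tree with lexicographic
tie-breaking orders the merges (making the result independent of input
order), and profiles are merged by affine-gap DP over columns with mean
sum-of-pairs BLOSUM62 scoring ("once a gap, always a gap"). This is not an
attempt to reproduce any particular MSA program's output; it is a
self-contained aligner whose two-sequence case provably attains the
global optimum and whose behavior on the package's indel-free synthetic
families is exact. At realistic family sizes (<= ~60 members, coil
fragments of a few dozen residues) it is entirely adequate; it does no
iterative refinement, so very gappy alignments of long, fast-evolving
full-length proteins are better delegated to a dedicated MSA tool, with
the result re-imported for the conservation and mapping steps.

Column conservation is classified on gap-free columns only (a gap
anywhere vetoes conservation) into the strictest satisfied class:
identical in all rows; all residues within one equivalence set (default
the single set `{I, L, V}`, the "structurally similar" trio - deliberately
not extended to M); identical within every taxon group; set-equivalent
within every group; else not conserved. Residue mapping between members
reads residue numbers off a shared column and is bijective wherever both
rows are ungapped.

By default the pipeline aligns scanner-derived coil fragments (the
conserved region, where the alignment is trustworthy at 17% full-length
identity); `align_full_length = TRUE` aligns whole members instead. The
published alignment figures do not state which was done; the fragment
default is the conservative choice.

## Trees

`nj_tree()` is canonical Saitou-Nei neighbor joining (via **ape**), exact
on additive matrices, with negative branch lengths clamped to zero
afterwards; tie-breaking among equal Q-criterion pairs follows ape's
deterministic implementation. Maximum-likelihood inference is out of
scope on purpose: the claim being operationalized is *topological
consistency* with a reference (core-gene) tree, which is quantified as the
Robinson-Foulds distance (via **phangorn**), i.e. the number of
non-trivial bipartitions unique to one tree. Distances default to
`1 - fraction identity` with pairwise deletion of gap columns; the Poisson
correction `-ln(1 - p)` is available where distances approach saturation.

## The synthetic-genome generator

Real alphabaculovirus records cannot ship with the package, so every
claim is tested against generated genomes with machine-checkable ground
truth (`simulate_genomes()` / `truth_check()`). The generator emulates the
study design:

* ~10 small circular genomes (default 40 single-exon CDS each; tests use
  14-16 genes to keep runtimes in seconds) in two taxon groups;
* an egt-like anchor (500 aa), a Bm9-like anchor (100 aa), and a family
  member (230 aa, the scale of the real proteins) placed between the
  anchors with 0-2 intervening genes and a random rotation of the
  circular gene order per genome;
* a planted 35-residue coil (5 heptads) in the member whose a/d core
  positions are constrained to `{I, L, V}`;
* deletions matching the observed census structure: by default the member
  is deleted in the last genome (the one-genome-without-a-homolog analog)
  and Bm9 in the two genomes before it;
* evolution by i.i.d. per-site substitution along a star tree (or any
  supplied tree), substitution probability = `divergence` x branch
  length, replacements uniform over the allowed residues. The default
  divergence 0.2/branch puts typical pairwise member identity near 66%,
  and the test conditions span 0.1-0.3. Uniform replacement (rather than
  BLOSUM-weighted) is chosen because the expected pairwise identity then
  has a closed form - `(1-p)^2 + p^2/k` per site with `k` alternatives -
  which the suite checks against simulation.

Two deliberate idealizations make the ground truth crisp, and bound what
passing tests prove:

* **Decoys are shared orthologous families.** All non-anchor, non-member
  genes descend from common decoy ancestors, one per genome, like the
  core genes that make up most of a real baculovirus genome. This keeps
  every best-hit decision competitive: in the genome whose member was
  deleted, every protein has a strong true ortholog back in the query's
  genome, so a family member's best *random* hit there cannot be
  reciprocated. Genomes consisting largely of unmatched, genome-private
  ORFs would defeat plain RBH in exactly that situation - a known
  limitation of the method itself, not of the implementation.
* **Indel-free evolution by default**, so ancestral residue numbering
  remains valid truth for the conservation and mapping tests, and the
  member's non-core positions are drawn from (and substitute within) the
  14 residues outside the hydrophobic set, so the planted coil and its
  constrained columns are exactly identifiable in the output. An
  `indel_rate` exists for stress tests only.

Consequently the tests demonstrate correctness of the machinery under the
stated model - not robustness to indel-rich alignment, compositional bias,
paralogous expansions beyond simple extras, or horizontal transfer. On
real data those effects are absorbed by the explicit thresholds, which is
why all of them are configuration, not constants.

## Numerical and degenerate-input choices

* All coordinates and residue numbers are 1-based inclusive; gene ranks
  are 0-based and consecutive after sorting by start.
* Spliced (`join(...)`) CDS are skipped with a warning rather than
  translated; alphabaculovirus CDS are essentially all single-exon, and a
  silently mistranslated join would poison downstream scores.
* Anchor/hit tie-breaking is total: score, then alignment length, then
  lexicographic gene id - so the pipeline is invariant to genome input
  order and to rotation of the circular records (both are tested).
* On a tie between the two circular arcs joining the anchors, the arc
  leaving egt in the forward direction is taken.
* "Downstream of egt" when Bm9 is absent is operationalized as a
  *symmetric* window because the published description does not fix a
  reading direction; a symmetric window cannot miss the true neighborhood
  at the cost of a few extra candidates.
* The empty local alignment (score 0) is a value; undefined percent
  identity on it is an error. Genomes with no usable CDS are errors;
  genomes without an egt anchor are skipped with a logged warning.
* Seeded runs restore the caller's RNG state (`simulate_genomes()` uses an
  isolated Mersenne-Twister stream), and a fixed seed yields byte-identical
  genomes, truth, and written files.

## Problem sizes in the test suite

The suite regenerates all fixtures at run time: alignment-oracle checks
enumerate every gapped alignment for ~400 random peptide pairs of length
<= 8; family-recovery checks run 20 fixtures of 6-10 genomes x 16 genes at
divergences 0.1-0.3; the remaining end-to-end checks use 4-10 genome
fixtures. These sizes keep the whole suite within a few minutes on one
CPU while exercising every code path; nothing in the implementation is
specific to them, and the generator defaults (40-gene genomes) are the
intended realistic scale.

## Known limitations

* RBH with raw-score thresholds has no significance model; on proteomes
  with many genome-private genes, deletion genomes can accrete spurious
  reciprocal hits (see the generator discussion above). A bit-score or
  E-value acceptance rule would be the natural extension.
* The heptad scanner does not predict oligomerization state and its
  interval boundaries are approximate by design.
* The progressive aligner does no refinement; for indel-rich families the
  coil-fragment default mitigates but does not remove alignment error.
* NJ on identity distances is a topology check, not a substitute for
  model-based phylogenetics; branch lengths should not be interpreted
  beyond that.
* The GenBank reader consumes only LOCUS metadata and single-interval CDS
  features with translations (or translatable spans); it is not a general
  feature-table parser.
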