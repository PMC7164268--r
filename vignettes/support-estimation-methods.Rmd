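---
title: "Sequential-resampling random walks and alignment support estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-resampling random walks and alignment support estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seres)
```

## The problem

Resampling-based support estimation generates replicates of the data, re-runs
the analysis on each, and reads support for a feature off the fraction of
replicates that recover it. The standard bootstrap draws sites independently
with replacement, which assumes sites are independent and identically
distributed. Biomolecular sequences violate that assumption routinely:
biochemical function, recombination, and especially insertion/deletion
history all make a residue's identity depend on its neighbors.

The Heads-or-Tails idea — an analysis should be repeatable whether an
alignment is read left-to-right or right-to-left — preserves that sequential
dependence but yields only two replicates. The SERES random walk generalizes
it: a walk along the sequence emits positions as it goes, reversing direction
with probability $\gamma$ (and with certainty at the ends). Every replicate
satisfies the **neighbor preservation property**: two residues adjacent in a
resampled sequence were adjacent in the original. $\gamma = 0$ started at
either end recovers exactly the two Heads-or-Tails readings; $\gamma > 0$
yields arbitrarily many distinct replicates.

## The aligned walk

`sample_aligned_trace(k, gamma)` walks over the $k$ sites of a fixed
alignment. Per step it emits the current site, updates the direction (forced
inward at sites $0$ and $k-1$, reversed with probability $\gamma$
elsewhere), and moves one site. The walk stops after emitting $k$ sites, so
replicates conserve alignment length. Start site and direction are uniform
by default.

Two numerical conventions matter:

* *Emit before reversing.* A boundary site is emitted exactly once per
  visit; emitting after the move would double-sample the ends.
* *Forced inward at the boundary.* At site $0$ or $k-1$ the next move is
  deterministic; applying the $\gamma$-reversal there could step off the
  alignment. `k = 1` is handled as a special case emitting site 0
  repeatedly.

The finite walk slightly under-samples the ends: the forced reversals
deplete a diffusive boundary layer (for walk length $k$, roughly the
outermost tenth of sites on each side), whose mass redistributes as a small
(~+6% at $k = 50$) excess over the interior. The tests therefore check
near-uniformity (±10% relative of $1/k$) on the interior excluding that
layer.

## Anchors, barriers, and the unaligned walk

Resampling unaligned sequences requires synchronization: all sequences must
traverse "the same place" together even though they have different lengths.
The package estimates **anchors** — high-similarity windows of a guide
alignment — and converts their boundaries into **barriers**, per-sequence
cut offsets, in the sense of parallel computing.

* Similarity is the average normalized Hamming distance (ANHD) over all
  sequence pairs, indels counted as mismatches. Two conventions the
  definition leaves open are fixed as: gap–gap cell pairs count as
  mismatches, and identical ambiguity codes count as mismatches unless
  `ambig_match = TRUE`. Neither matters for selected anchors, which are
  restricted to fully gap-free windows so that every anchor boundary maps
  to one well-defined offset per sequence.
* Selection is greedy by ascending ANHD, ties broken by leftmost start
  column, subject to a minimum spacing measured between nearest window
  edges in aligned columns. Defaults: $\lfloor k/20 \rfloor$ anchors of 5
  columns, spaced at least 25 columns; when fewer can be placed the maximal
  feasible set is returned with a warning.

`sample_unaligned_replicate()` then walks on barrier space. Each traversal
between neighboring barriers appends, for every sequence, the residues
between the two cut points — in natural order moving right, in *reversed*
order moving left. Reversed appending is the only orientation that preserves
neighbor adjacency across traversal boundaries, and because the flip is
global the sequences stay synchronized. Direction reverses with certainty at
the trivial start/end barriers, else with probability $\gamma$; termination
is checked only at barrier arrivals (segments are atomic, partial segments
would break synchronization) once the longest resampled sequence reaches
`length_factor` times the longest input. The default `length_factor = 1`
mirrors the aligned walk's length conservation; at least one traversal is
always performed. Anchor interiors are ordinary segments — anchors serve
only to place barriers and are otherwise unused.

## Support estimation

`run_support_pipeline()` re-aligns each resampled replicate and scores every
residue-pair homology of the input alignment by the fraction of replicates
that recover it. Because walk replicates can sample a residue more than once
(or not at all), two choices are fixed:

* *Binary per-replicate support*: a replicate supports a pair if at least
  one column of its re-estimated alignment co-aligns occurrences of the two
  original residues. This reduces to classic GUIDANCE scoring when every
  residue is sampled exactly once.
* *Co-sampling denominator* (default): the score divides by the number of
  replicates in which both residues were sampled at all, so pairs near
  sequence ends — which the walk visits less often — are not deflated; a
  total-replicate denominator is available, and pairs never co-sampled get
  `NA` (substituted by 0 in the pipeline: no evidence, no support).

The i.i.d. baseline (`method = "bootstrap"`, column resampling with
replacement) and an aligned-walk mode are run through the identical
degap–realign–score path, so the three resampling schemes are directly
comparable. Externally generated replicate alignments can be pooled by
calling `pair_support()` on a combined replicate list.

Re-alignment uses either an external command (e.g.
`aligner_external("mafft --auto {in} > {out}")`) whose output is verified to
degap back to its input, or the package's deterministic star aligner:
pairwise Needleman–Wunsch (match $+1$, mismatch $-1$, gap $-2$, tie-break
diagonal > up > left) merged around the centroid sequence, insertions
left-justified in per-slot blocks. The star aligner exists so the whole
pipeline runs and tests deterministically with no external binary; it does
not align insertions against each other and is not a competitive MSA tool —
results with it should be read as a lower bound on replicate-alignment
quality.

## Evaluation

Support scores are evaluated against a reference alignment by confusion
counts, ROC and PR curves, and their AUCs. Only homologies present in the
estimated alignment are in scope; reference homologies the estimate misses
are not considered. A positive call is support ≥ threshold. Precision at
$tp + fp = 0$ is defined as 1 for the curve endpoint; an empty negative
class degenerates the ROC curve with a warning. ROC-AUC uses the trapezoid
rule (and equals the normalized Mann–Whitney statistic, which the tests
verify); PR-AUC uses right-step summation, consistent with average
precision. Multi-dataset summaries can pool all scored pairs or average
per-dataset AUCs — both are exposed because the conventions differ and the
choice is not standardized.

## The simulator

`simulate_dataset()` emulates an indel-aware sequence-evolution study
design: a birth–death topology (pure-birth by default — the shape barely
matters because branch lengths are redrawn Uniform(0,1) and rescaled so the
root-to-furthest-leaf height equals the target exactly), GTR substitutions,
and an indel process, with homology tracked through every event so the true
alignment is known.

Parameter choices where the emulated design leaves values unstated:

* *GTR parameters* default to a generic transition-biased model
  (exchangeabilities 1, 3, 1, 1, 3, 1; frequencies 0.30/0.20/0.20/0.30),
  normalized to one expected substitution per site per unit time. Fully
  overridable.
* *Gap lengths* default to geometric with mean 4 residues — a plausible
  "medium" indel-length scale; the sampler is pluggable.
* *Indel events* follow a Gillespie process per branch (insertion rate
  $r_i(L+1)$ over slots, deletion rate $r_i L$ over sites, relative to
  substitution rate 1 per site); substitutions are applied analytically per
  site for its exposure time via the spectral decomposition of $Q$.
  Deletions truncate at the sequence end. Inserted residues start from the
  stationary distribution and receive fresh true-alignment columns placed
  next to their insertion anchor.

What passing tests on this generator do *not* show: the simulator has no
rate heterogeneity across sites, no empirically calibrated indel-length
distribution, and the built-in star aligner is far weaker than production
MSA tools, so absolute AUC values are not comparable to studies using
re-estimation with real aligners — only the *relative* behavior of
resampling schemes under identical treatment is meaningful here. One
summary-statistic caveat: `summary_stats()` reports ANHD under the anchor
convention (every gap cell, including gap–gap pairs, is a mismatch), which
runs substantially higher on gappy alignments than divergence measures that
ignore shared gaps.

## Problem sizes used by the tests

The test suite exercises the full pipeline at reduced scale, chosen as the
smallest sizes at which every property is still meaningfully tested:
10-taxon datasets with root length 200–300 and tree height 1 (a
moderate-to-high-divergence regime), 25 replicates per support run against
the standard 100, 1000 walk replicates for the neighbor-preservation and
termination properties, and 10,000 walks for the sampling-uniformity check.
`scripts/acceptance.R` runs the same study at 6 datasets × 30 replicates.
Deterministic seeding (one child seed per replicate index, derived from a
master seed by a stable counter scheme) makes every run reproducible and
makes the first $n$ replicates of a run a prefix of any longer run.

## Known limitations

* The star aligner is test-grade; use an external aligner for real data.
* Nucleotide–indel pair support is not implemented; scoring is
  residue-pair only.
* Anchor discovery needs a guide alignment (semi-parametric); alignment-free
  anchor discovery is not provided.
* At high divergence few gap-free guide windows exist, so fewer anchors
  than $\lfloor k/20 \rfloor$ may be placed, reducing walk diversity on
  exactly the datasets where support estimation is hardest.
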