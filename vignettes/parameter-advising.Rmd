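---
title: "Parameter advising for reference-based transcript assembly"
author: "TranscriptAdvisor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter advising for reference-based transcript assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TranscriptAdvisor)
```

## The problem

Reference-based transcript assemblers (Scallop, StringTie) reconstruct a
transcriptome from aligned RNA-Seq reads. Both tools expose many tunable
parameters — 18 for Scallop, 9 for StringTie — and the shipped defaults
are tuned for an average input. Individual samples differ in depth,
library preparation, and aligner behavior, so a single fixed parameter
vector leaves accuracy on the table, while hand-tuning per sample does
not scale.

*Parameter advising* is an a posteriori answer: run the assembler once
per parameter vector in a precomputed **advisor set**, score every
candidate assembly with an **accuracy estimator**, and keep the assembly
that scores best. The candidate runs are independent, so with enough
processors the wall-clock cost over a single run is just the scoring.
This package implements the full advising stack: the estimator, advisor
set construction by coordinate ascent, compact subset selection,
adapters for the two assemblers, and a deterministic mock assembler plus
synthetic-data generators that make every stage testable without
external binaries or real reads.

## The estimator: scaled AUC against a reference transcriptome

Candidate assemblies are compared with a curated reference
transcriptome. A multi-exon predicted transcript counts as a true
positive when some reference transcript on the same chromosome and a
compatible strand has an identical **intron chain** (the ordered intron
intervals `(end(e_i)+1, start(e_{i+1})-1)`); exon termini are allowed to
differ. A single-exon prediction matches a single-exon reference
transcript when their reciprocal overlap — overlap length divided by the
longer transcript's length — is at least `singleExonOverlap` (default
0.8). Strands are compatible when equal or when either is unknown
(`"*"`, written `"."` in GTF).

Every prediction carries a coverage value (the assembler's abundance
estimate) used as a confidence score. Sweeping a threshold *t* over the
distinct coverage values, keeping predictions with coverage ≥ *t*,
yields one point per threshold:

- sensitivity(t) = distinct reference transcripts matched by kept
  predictions / reference size,
- precision(t) = matched kept predictions / kept predictions.

The estimator is the trapezoidal area under precision as a function of
sensitivity, multiplied by 10^4. Reference transcriptomes are far larger
than what any single sample expresses, so sensitivities — and therefore
raw areas — are tiny; the 10^4 scale keeps the numbers readable, and all
AUCs in this package are reported on that scale. A perfect assembly (all
reference transcripts recovered, no false positives) scores exactly
10^4.

Details of the curve construction that were genuinely open and are fixed
here as package policy:

- Thresholds are **all distinct coverage values**, in decreasing order;
  absent coverage sweeps as 0. An optional `bins` argument collapses the
  sweep to a fixed number of quantile thresholds for cross-checking
  against external fixed-binning tools.
- The curve is anchored at `(0, precision of the highest-threshold
  point)` and is not extrapolated beyond the lowest threshold; this is
  the minimal-assumption trapezoid rule, and the test suite's
  independent oracle uses the same convention.
- Duplicate sensitivity values contribute zero-width segments. Several
  predictions matching the same reference transcript all count toward
  precision but only once toward sensitivity.
- Identical predicted intron chains are **not** deduplicated before
  scoring.
- Predictions on chromosomes absent from the reference are unmatched,
  not errors.
- Matching ties resolve to the lexicographically smallest reference id,
  making labels deterministic.

Coordinates are 1-based inclusive everywhere (the GTF convention); no
half-open conversion exists anywhere in the public data model, which
removes a whole class of off-by-one bugs.

```{r estimator}
ref <- generateReference(nGenes = 50, seed = 1)
asm <- generateAssembly(ref, tpFraction = 0.4, fpCount = 20, seed = 2)
assemblyAUC(asm, ref, curve = TRUE)
```

## Learning advisor sets by coordinate ascent

For one training sample, `coordinateAscent()` maximizes the estimator
over the assembler's parameter space, starting from the default vector.
Passes run over the parameters in declaration order; for each parameter
the proposals are the two single-step moves `value ± step` clamped to
bounds (numeric; an optional multiplicative mode proposes `value × step`
and `value / step` for scale-like parameters), the flip (boolean), or
every alternative choice (categorical). Under the default
`best-of-both` policy all proposals for a coordinate are evaluated and
the best is accepted iff it beats the incumbent by **strictly** more
than `minImprovement` (default 0); equal-score moves are rejected, which
guarantees termination. A pass with no accepted step ends the search;
`maxPasses` (default 20) caps the run. The objective is memoized, so no
parameter vector is ever evaluated twice, and a failed assembler run
scores 0 with a warning (an error on the start vector propagates,
because a broken default means a broken setup). Single-step proposals
rather than line searches keep the per-pass budget predictable — at most
two evaluations per numeric coordinate — at the cost of needing one pass
per step of travel; callers crossing wide boxes should raise
`maxPasses` accordingly.

Gradient-free alternatives (simulated annealing, random restarts) were
deliberately left out: the empirical parameter landscapes of these
assemblers show very few local maxima, so a single deterministic start
from the default suffices, and determinism makes every run reproducible
bit for bit. A bimodal mock landscape (`optimum2`) exists specifically
to probe what happens when that assumption fails.

`buildAdvisorSet()` runs one ascent per training sample, deduplicates
the resulting vectors, and by convention prepends the default vector in
position 1. `advise()` breaks score ties by the earliest position in
the set, so including the default first makes "never worse than the
default" a structural guarantee rather than a statistical one.

## Compact subsets

When resources do not allow running the full advisor set,
`greedySubsets()` selects nested subsets on a training **AUC matrix**
(samples × vectors, entries scaled AUC): the advising score of a subset
is the mean over samples of the best entry among its columns, the
size-1 subset is the argmax singleton, and each extension adds the
column with the largest marginal gain, ties to the lowest index. Greedy
forward selection was chosen over exact combinatorial machinery because
the advising score is monotone submodular in the subset, giving the
classical (1 − 1/e) guarantee, and because an exhaustive mode
(`exhaustiveSubset()`, with an enumeration budget) covers the small
instances where exactness matters — it doubles as the oracle the greedy
path is tested against. Whether subsets must contain the default vector
is left to the caller (the default-first convention applies only to
sets built with `includeDefault = TRUE`).

## The mock assembler and synthetic data

The mock assembler makes the whole stack runnable in seconds with no
BAMs and no external binaries. A `mockLandscape()` plants an optimum
`p*` and per-parameter weights `w`; the quality of a vector `p` is

    quality(p) = exp(-sum_i w_i * d_i(p, p*)^2)

with `d_i` the distance in step units (numeric) or 0/1 (boolean,
categorical) — separable and unimodal, matching the observed structure
of the real assemblers' landscapes. Given a sample seed, the mock
assembler copies `round(quality * maxSensitivity * |reference|)`
reference transcripts as true positives (under a seed-derived fixed
priority) and adds `round(fpMax * (1 - quality))` false positives made
by moving one intron boundary of a reference transcript by at least two
bases (so they can never accidentally match; perturbed chains are also
checked against the whole reference chain set). True-positive coverages
are log-normal with mean ~10, false positives ~2, so threshold sweeps
produce non-trivial curves. The per-sample priority order, coverages
and false-positive pool are fixed per sample seed and shared by all
vectors, which makes the mock AUC a monotone function of quality alone
and the advising experiments noise-free. With `sampleShift = TRUE`,
each sample seed deterministically displaces two numeric coordinates of
`p*` by one or two steps — different samples genuinely favor different
parameter vectors, which is the premise advising rests on.

`generateReference()` emulates a reference transcriptome: genes placed
without overlap across chromosomes, one to a few isoforms per gene
sharing a locus but with pairwise distinct intron chains, a
configurable fraction of single-exon transcripts, uniform exon and
intron lengths. `generateAssembly()` plants an exact true/false
positive structure for estimator tests.

What the synthetic path does **not** emulate: read-level noise and
coverage-dependent assembly artifacts, expression realism, incomplete
or erroneous references, overlapping genes, and novel true transcripts
absent from the reference (which the estimator by construction counts
as false positives). Passing tests therefore demonstrate the
correctness of the advising machinery — matching, curve construction,
optimization, selection, reproducibility — not the biological
performance of advising on real samples, which requires real BAMs and
the external assemblers via `scallopAdapter()` / `stringtieAdapter()`.

## Numerical and engineering choices

- **Scale**: all AUCs on the ×10^4 scale, including ratios' numerators
  and denominators, so printed values are directly comparable across
  tools and figures. Medians, not means, are the headline summaries.
- **Determinism**: every generator and the mock assembler are pure
  functions of their declared seeds; RNG state is saved and restored
  around internal draws, so library calls never perturb a caller's
  random stream. Identical inputs give byte-identical GTFs.
- **Grid arithmetic**: numeric grids are `lower + k * step` with the
  point count computed with a 1e-9 slack to absorb floating-point
  division error; sampled values are clamped to the upper bound.
- **Degenerate inputs**: an empty prediction set yields an empty curve
  and AUC 0; an empty reference is an error (sensitivity undefined);
  all-zero rows in an AUC matrix are retained and flagged; a default
  vector with AUC 0 makes that sample's advising ratio undefined — it
  is reported as `NA` and excluded from the median with a warning.
- **Problem sizes**: the test suite and the acceptance script run at
  desk scale — references of 15–100 genes (~30–200 transcripts),
  assemblies of up to ~100 predictions, 10 training samples, advisor
  sets of ~11 vectors, 4-parameter mock spaces — sizes chosen so the
  full suite exercises every stage end to end in a few minutes while
  leaving the oracle comparisons exhaustive.
- **Coverage attribute**: which GTF attribute holds the confidence
  score is assembler-dependent; the reader tries `cov`, `coverage`,
  `FPKM` in order (configurable), since both supported assemblers write
  `cov`. Non-numeric coverage values are downgraded to "absent" with a
  warning to tolerate third-party GTF dialects.
- **Shipped parameter spaces**: `inst/extdata/` carries YAML
  declarations for Scallop (18 parameters) and StringTie (9),
  transcribed from each tool's command-line documentation and versioned
  per release in the file headers; bounds and steps there define the
  coordinate-ascent search lattice, not hard limits of the tools.

## Limitations

The estimator is bounded by the completeness of the reference: a novel
true transcript reduces precision by definition, so advising optimizes
agreement with current annotation, not novelty discovery. Coordinate
ascent takes one step in one coordinate at a time; it cannot exploit
parameter interactions within a pass and may overfit each training
sample (which the advising-set construction turns into diversity rather
than a defect). The single-exon overlap rule is a fuzzy stand-in for
exact equivalence and its 0.8 default is a convention, configurable and
logged. Real-adapter behavior (flag rendering against actual Scallop /
StringTie releases) is exercised only in optional integration runs,
never in the default suite.
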