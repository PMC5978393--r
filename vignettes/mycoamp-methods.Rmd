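---
title: "Methods: processing variable-length ITS amplicons with spike-in calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processing variable-length ITS amplicons with spike-in calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoamp)
```

## The problem

High-throughput amplicon sequencing of the fungal rRNA internal transcribed
spacer (ITS) differs from 16S work in one decisive way: ITS1 and ITS2
amplicons vary widely in length (roughly 100-600 bp). Pipelines built around
uniform-length amplicons truncate all reads to a fixed length and *discard*
anything shorter — which silently deletes genuinely short taxa from the
community. A second, subtler problem is tag-switching (index bleed): a small
fraction of reads is assigned to the wrong sample's barcode, inflating
apparent diversity precisely because read counts are then interpreted
presence/absence-wise. mycoamp implements a processing chain designed around
both problems, plus a designer for non-biological synthetic spike-in
communities (SynMock) that make tag-switching measurable, and a run
simulator that gives every stage a closed-loop test with known truth.

## Pre-processing model

Reads from single-file barcoded platforms have the layout
`barcode + forward primer + insert + rc(reverse primer) [+ rc(3' barcode)]`.
`demux_single()` applies, in order:

* **Barcode matching** — anchored at the 5' end, compared by edit distance,
  default tolerance **0 edits**. Reads tying two barcodes at the same best
  distance are rejected as ambiguous rather than guessed; since the whole
  point of the downstream filter is to quantify mis-assignment, guessing at
  demultiplexing would contaminate the signal.
* **Forward primer** — required, default tolerance **2 edits**. Edits are
  full edit distance (substitutions *and* indels) because homopolymer-prone
  flow platforms produce indels; a substitution-only mode is available
  (`indels = FALSE`). IUPAC codes in the primer match their expansions at
  zero cost.
* **Reverse primer** — searched as its reverse complement in the remaining
  sequence; removed when found, and its presence recorded, because it is the
  evidence that a short read is a complete short amplicon rather than a
  truncated artifact.
* **Lossless trimming** — with `max_len = 300` (the conventional read-length
  setting): reads longer than 300 bp are truncated to exactly 300; reads at
  or under 300 bp are kept *unchanged* if their reverse primer was found and
  rejected otherwise (`keep_no_revprimer = TRUE` relaxes this). Two
  alternative modes exist for comparison: `pad` (N-pad short reads to the
  threshold; padded bases carry a neutral high quality so the
  expected-error statistic is not distorted) and `truncate` (the hard
  truncate-and-discard behavior of uniform-length pipelines). The package's
  recovery experiment — 40 synthetic references with lengths spanning
  150-550 bp — shows `fulllength` and `pad` recover every reference after
  clustering while `truncate` loses every reference shorter than the
  threshold.

Coordinates throughout are 1-based inclusive, the R convention.

Paired-end input is merged by `merge_pairs()`: best ungapped overlap of at
least 12 bp with at most 5% mismatches; at each disagreement the
higher-Phred base wins and the consensus quality is the maximum of the two.
An ungapped scan is adequate at amplicon scale because the two mates come
from one molecule: true indel disagreement within an overlap indicates a
bad pair, which the mismatch cap rejects.

## Clustering and the pre-filter table

Quality filtering uses expected errors, `EE = sum(10^(-q/10))`, with the
conventional cap of 1.0 — but **only to select the clustering input**.
Clustering is greedy centroid formation in abundance order (UPARSE-style):
dereplicated uniques with abundance >= `min_size` (default 2) either join
the first centroid at global identity >= **0.97** (inclusive) or found a new
OTU. Global identity is Needleman-Wunsch with match +1, mismatch -1, linear
gap -2, **with terminal gaps penalized** and counted in the denominator
(identity = matches / alignment columns): with variable-length amplicons a
terminal overhang is real disagreement, not noise to clip.

The OTU table is then built by mapping the **pre-quality-filter**
demultiplexed reads to the centroids (best hit at >= 0.97, ties to the more
abundant centroid for determinism). This separation matters: EE filtering
biases against longer reads (more bases, more expected errors), so counting
only filtered reads would distort abundances by length. Counting the
demultiplexed reads keeps the table representative of what was in each
sample. `min_size` excludes singleton uniques from *seeding* centroids, but
their reads still count in the table through mapping.

The chimera check is a deliberately simplified two-parent crossover test,
not UCHIME: a candidate is flagged when some split point leaves its prefix
matching one centroid and its suffix a different centroid, each at >= 99%
ungapped segment identity, while no single centroid explains the full
length at >= 97%. It catches the clean PCR crossovers the simulator (and
mock mixtures) produce; partial-identity chimeras with additional errors
can slip through, as they do in production denoisers.

`rarefy()` performs without-replacement subsampling to a fixed depth per
sample. It is provided for comparability with common practice; since PCR
bias already decouples read abundance from template abundance (see below),
rarefied counts inherit that caveat and the package's own analyses treat
tables presence/absence-wise after filtering.

## Tag-switching estimation and filtering

With a spike-in mock sequenced alongside the samples, `map_otus_to_mock()`
classifies each OTU against the mock reference (hit at >= 97%, variant in
[90%, 97%), chimera-suspect, or non-mock), and `estimate_bleed()` measures
tag-switching in both directions:

* into the mock sample: foreign-OTU reads / total reads in the mock sample;
* out of the mock: mock-hit OTU reads found in other samples / total
  mock-hit reads. Mock *variants* are excluded from this numerator and
  denominator because they may be chimeric artifacts rather than switched
  tags (configurable).

The applied rate defaults to the **maximum** of the two. The choice of
combination rule is genuinely open — a single summary rate must stand in
for two asymmetric processes — and the maximum is the conservative choice:
it can only over-filter cells that are already within the range attributable
to mis-assignment. `--bleed-combine {max, mean, in, out}` exposes the
alternatives, and a user-supplied rate supports runs without a spike-in.

`filter_table()` zeroes, per OTU, every cell strictly below
`ceiling(rate * OTU total)`; cells at or above the threshold are untouched,
so low-abundance OTUs are never dropped wholesale. Thresholds are computed
once from the *original* table totals and then applied — recomputing totals
after zeroing would make the filter non-idempotent. `ceiling` rather than
rounding errs on the side of removing borderline cells. The mock rows and
the mock sample column are removed afterwards.

The error-rate metric mirrors the standard mock-community report:
`100 * total mismatches / total aligned bases` over mock-hit OTUs, where
mismatches count substitution and gap columns of the global alignment.

## Taxonomy

Three assignment routes are combined:

1. **Global-alignment top hit** (exhaustive at desk scale, lexicographic
   ties): identity strictly above 0.97 keeps the top hit's lineage. Note
   the deliberate asymmetry with clustering: the clustering threshold is
   inclusive (>= 0.97) while this rule is strict (> 0.97), matching the
   respective conventions.
2. **k-mer bootstrap classifier** (SINTAX-family scheme): per bootstrap,
   32 8-mers are drawn with replacement from the query's k-mer set, each
   reference scored by shared count, and the winner's lineage recorded.
   Confidence at a rank is the fraction of 100 bootstraps agreeing with the
   modal winner down to that rank (hence non-increasing), reported down to
   the deepest rank with confidence >= 0.8. Parameters k = 8, m = 32,
   B = 100, cutoff 0.8 are that family's conventions. Only this one
   classifier is implemented, so "best classifier confidence" reduces to
   its output.
3. **Least common ancestor**: when the alignment and classifier lineages
   disagree at a rank both have set, the reported lineage truncates to
   their longest common prefix — a conservative consensus.

Reference databases are FASTA with rank-prefixed lineages in either the
`;tax=k:...,p:...` or the `k__...;p__...` header dialect, auto-detected.

## The SynMock designer

Each designed member is
`SSU anchor + ITS1_i + 5.8S segment + ITS2_i + LSU anchor`. The anchors
carry real conserved priming sites — ITS1-F and ITS1 in the SSU anchor; a
5.8S segment opening with the ITS3 site (the reverse complement of the ITS2
priming site) and closing with a concrete expansion of fITS7; the LSU
anchor opening with the reverse complement of ITS4 — so the members amplify
and extract exactly like real ITS sequences with either primer pair. The
variable regions are random sequences under constraints: GC in [0.40,
0.65]; homopolymers capped at 5 bp except planted 7 bp and 9 bp runs in
designated members (so flow-platform homopolymer behavior is probed); all
pairwise identities over the variable regions at most 0.90. Region lengths
are assigned as an evenly spaced ladder across ITS1 150-300 bp (ascending)
and ITS2 140-360 bp (descending) rather than drawn uniformly: the set then
always contains a short (~140-160 bp) ITS2 member — the kind that hard
truncation deletes — and a long member near platform limits, while total
amplicon lengths still vary. Generation is rejection sampling (capped at
10,000 attempts, erroring with the violated constraint); the design is a
pure function of its seed. No published per-member length/GC targets exist
for such communities, so these defaults are representative rather than
canonical, and every constraint is user-adjustable through
`synmock_spec()`.

## The run simulator

`simulate_run()` emulates the facts of amplicon sequencing that the
pipeline must survive, with per-read truth recorded:

* **PCR bias**: a log-normal multiplicative factor per template and run
  (`exp(N(0, sigma))`), applied to the composition and renormalized.
  The observation being emulated is that an equimolar template mixture
  yields far-from-equimolar reads, with the distortion set at the initial
  PCR; log-normal is chosen for positivity and heavy tail, not from a
  mechanistic model. At sigma = 1 an equimolar 12-template community
  typically shows a > 3-fold max/min read-count ratio.
* **Read errors**: binomial substitutions per base, and +/-1 bp indels
  adjacent to homopolymer runs >= 3 bp (the flow-platform signature).
  Erroneous bases receive low Phred scores (Q3) on a Q38 background so
  expected-error filtering interacts with planted errors as it would with
  real data.
* **Tag-switching**: a binomial fraction of reads has its observed sample
  reassigned uniformly among the other samples. This models the observable
  consequence without committing to a mechanism (none is established); a
  dual-index mode can optionally boost switching between samples sharing
  an i7 index, emulating the reported shared-index effect (off by
  default).

`make_biomock_fixture()` generates a pseudo-biological stand-in for a
plasmid mock of cloned ITS fragments — 26 templates with lengths laddered
over 237-548 bp and GC over 0.438-0.684, exactly one pair at ~96% identity
(an intragenomic-variant pair that legitimately clusters into two OTUs)
and one member with two 9 bp homopolymer runs. It is synthetic and labeled
as such; it reproduces the *shape* of such a community, not its sequences.

## What the closed-loop tests do and do not show

The simulator gives every stage a ground truth: demultiplexing counts are
checked against the truth table exactly; a zero-error run must be
reproduced read-for-read through clustering and mapping; an injected 0.5%
tag-switch rate across 8 samples of 50,000 reads must be re-estimated
within +/-50% and its bleed-origin reads reduced >= 90% by filtering. Those
problem sizes (and e.g. 10-20 seeds for stochastic checks, 40 references
for the length-recovery experiment, 500 random cases per brute-force
oracle) were chosen as the smallest sizes at which the binomial/order-
statistic arguments above give comfortable margins.

Two caveats bound what passing means. First, the simulator's error model is
simpler than real flowgram error structure, its bleed destinations are
uniform, and chimera formation is not simulated during PCR (chimeras are
constructed explicitly in tests) — so the tests validate the *logic* of the
stages, not platform-specific error calibration. Second, the bleed filter
can only remove switched reads that land in otherwise-quiet cells; a
switched read landing on an OTU legitimately abundant in the destination
sample is invisible to any count-threshold method. The closed-loop filter
test therefore uses disjoint per-sample compositions, which is exactly the
situation the non-biological spike-in is designed to create for itself.

## Numerical and degenerate-input choices

* Identity thresholds: clustering/mapping inclusive (>= 0.97), taxonomy
  rule strict (> 0.97), as above.
* Ties: equal-best barcode -> reject ambiguous; equal-identity mapping ->
  first (most abundant) centroid; equal-score classifier winner ->
  lexicographically smallest reference id. All ties are resolved
  deterministically so a run is a pure function of inputs, configuration
  and seed.
* Alignment columns are recovered from `la + lb - matches - substitutions`,
  an identity that avoids materializing aligned strings.
* Empty inputs: empty read sets write empty files and produce all-zero
  tables; empty sequences, primers and references are errors.
* Rarefaction drops (and reports) samples below the requested depth;
  sampling is seeded and exact.
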