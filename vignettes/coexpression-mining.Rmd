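---
title: "Methods: mutual-rank co-expression mining and screen evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-rank co-expression mining and screen evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexminer)
```

## The mining model

`coexminer` operationalizes guilt-by-association discovery of pathway
regulators. The underlying biological assumption is that a transcription
factor driving a biosynthesis branch is transcribed under the same
conditions as its target genes, so across a sufficiently diverse
expression atlas (organs, treatments, perturbation lines) the regulator
sits near its targets in co-expression space. The procedure makes that
operational in four steps.

**Similarity ranking.** Expression is log2-transformed
(`log2(TPM + log_offset)`, offset 1 by default) and pairwise similarity is
Pearson correlation, with Spearman as an option. Pearson on log-TPM is the
common choice for bulk co-expression atlases: the log stabilizes the
strong mean–variance relationship of TPM values, after which linear
correlation captures proportional co-regulation; Spearman is offered for
atlases with strongly non-linear responses. Each gene's neighbors are
ordered by descending similarity, so `r(A→B)` is the rank of B among all
other rankable genes from A's point of view — a quantity robust to the
absolute correlation level, which varies with atlas composition.

**Mutual rank.** Directed ranks are asymmetric (`B` may be `A`'s best
neighbor while `A` is `B`'s 400th). The symmetric edge weight is the
geometric mean `MR(A,B) = sqrt(r(A→B) · r(B→A))`, the established
mutual-rank statistic for co-expression networks. Mutual ranks are
computed from the *full* orderings, not truncated at k: an edge can enter
the KNN graph through one direction only, and its weight must still
reflect the other direction's true rank. `MR ≥ 1` always, with equality
exactly for reciprocal rank-1 pairs.

**KNN network.** Each gene is connected to its top k = 500 most
co-expressing genes. The undirected network is the union symmetrization —
an edge exists when either endpoint lists the other — because "connect
each gene to its top k" is a directed prescription and the union preserves
every such connection. Out-degree is ≤ k by construction; in-degree is
unbounded (hub genes).

**Candidate selection.** For each bait (a pathway gene with known branch
membership), the bait's top-k neighborhood is intersected with an
annotated regulator list; survivors are ordered by the bait's neighborhood
rank and truncated to `cap = 10`. The cap uses the *directed* bait→gene
rank, not the mutual rank, because the question asked per bait is "which
regulators does this bait co-express with most strongly" — a directed
notion. The per-bait lists are unioned; duplicates collapse but all
(candidate, bait, rank) associations are retained, since the bait-profile
of a candidate is what drives grouping and interpretation. A bait is never
its own candidate; other baits may be candidates (known TFs sit in bait
panels and must remain discoverable). With 44 baits and cap 10 the
selection is bounded by 440 candidates; overlap between neighborhoods
makes real lists substantially shorter.

## Screening-group assembly

Combinatorial screens co-overexpress up to `max_size = 4` candidate TFs
per infiltration to raise throughput. Historically such grouping is done
by eye from the candidate × bait matrix; `assign_groups()` replaces that
with a deterministic greedy procedure so runs are reproducible: candidates
are represented by their bait-association sets, ordered by descending
association count (ties by id); each group is seeded with the first
unassigned candidate and filled with the remaining candidates most similar
to the seed by Jaccard similarity of bait sets, requiring similarity > 0
to merge. Disjoint-profile candidates therefore stay in separate groups
and identically-profiled candidates group together. This is a design
stand-in for a manual step — any fixed grouping of the published screen is
*not* a reproduction target — and the greedy seed-first rule was chosen
over global clustering because it is transparent, order-independent given
the explicit ordering, and exactly enumerable in tests.

## qPCR quantification and the advancement gate

Relative quantification follows the standard multi-reference-gene scheme:
per gene `RQ(g, s) = E_g^(meanCq_g − Cq(g, s))` (the gene's mean Cq over
all samples as calibrator), per sample a normalization factor `NF(s)` as
the geometric mean of the reference genes' RQs, `NRQ = RQ / NF`, then a
per-gene rescale so the control-condition mean is 1. Two invariances make
this arithmetic trustworthy and are asserted in tests: a uniform Cq shift
of any reference gene cancels exactly, and a uniform shift of a target
gene across all samples leaves its fold changes untouched. Amplification
efficiency defaults to E = 2 (100%) with per-gene overrides; efficiencies
≤ 1 are rejected.

Fold changes are geometric-mean ratios, equivalently `2^Δmean` on log2
NRQ, and p-values come from the classic equal-variance two-sample t-test
on log2 NRQ — log2 first, because NRQs are ratio-scale and approximately
log-normal, and the equal-variance (not Welch) form because screens use
small, balanced replicate groups. The advancement gate is: every
introduced TF overexpressed strictly > 5-fold, and at least one pathway
target strictly > 2-fold with p strictly < 0.05. Strict inequalities are
deliberate (the rule is stated as exceedance); requiring *every* TF of a
group to clear the overexpression bar is a design choice — a group with a
failed overexpression is uninterpretable, so it must be re-tested rather
than advanced. No multiple-testing correction is applied inside the gate:
the screen is a triage step whose hits are re-tested individually, and
correction would trade false negatives for a guarantee the follow-up
provides anyway. This is a caveat to keep in mind when reading per-target
p-values as evidence.

## The synthetic-data generator

`simulate_atlas()` emulates the statistical structure the analysis relies
on, not any particular organism's transcriptome. Modules (pathway genes +
planted regulators) share an activity profile over samples; the default
profiles are block designs (`block_profile()`) mimicking organ/treatment
contrasts, which is what decouples pathway branches in real atlases.
Multiplicative log-normal noise (sd `noise_sd` on the natural-log scale,
default 0.25; 0.05 in recovery tests) is applied per gene per sample
before each column is rescaled to `tpm_total = 1e6` (TPM closure).
Background genes get per-gene log-normal profiles (sd 1) independent of
every module, so they are variable — hence rankable — but uncorrelated
with pathway structure.

Within a module, genes at zero noise are exactly proportional (one shared
baseline per module). This is deliberate: it makes within-module Pearson
correlation of the log-transformed matrix exactly 1 even through the
`+ offset` of the log transform and the per-column TPM rescaling, which
gives the test suite a sharp, assertable signal instead of an approximate
one. Per-gene expression-level differences therefore enter only through
the noise term. What the generator does *not* emulate: count noise at low
expression, batch effects, correlated background structure (housekeeping
programs), 3' bias, or library-size artifacts. Passing recovery tests on
these atlases shows the machinery is correct — ranks, caps, unions and
gates do what they claim — not that recall would be 1.0 on a real
compendium, where regulator–target correlation is diluted by everything
above.

`simulate_qpcr()` generates Cq values so the expected efficiency-corrected
ratios equal specified true fold changes: a fold change f shifts Cq by
`−log(f)/log(E)` cycles. Noise (`cq_sd`, cycles) acts per biological
replicate; optional technical-replicate noise (`tech_sd`, default 0, with
`n_technical = 2` measurements) is averaged out before export, mirroring
how instruments report per-biological-replicate Cq. With all noise at 0
the downstream quantification is exact (asserted to 1e-9), which pins the
NRQ arithmetic independently of statistics.

## Numerical and degenerate-input choices

- **Tie-breaking** in rankings: descending similarity, then ascending
  gene id. Ids are opaque strings; sorting on them makes rankings
  invariant to input row order, which is asserted by permutation tests.
- **Zero-variance genes** (all-zero or constant) have undefined
  correlation; they are excluded from ranking with a message, carried
  through as `excluded`, and any query against them errors with the gene
  named rather than silently returning 0.
- **k truncation:** `k = 500` against an atlas with fewer than 501
  rankable genes is truncated to n − 1 (the pipeline logs this), so small
  synthetic atlases exercise the same code path as full-size ones.
- **Absence vs rank:** the candidate × bait relative-rank matrix stores
  `rank/k ∈ (0, 1]` and masks absent pairs as NA — absence is not rank 0,
  which would read as the strongest possible association.
- **Degenerate t-tests:** when both groups have zero variance the p-value
  is defined as 1 for zero difference and 0 otherwise, so noise-free
  fixtures evaluate without NaN.
- **Determinism:** every stochastic step is governed by an explicit seed
  through a private RNG stream that restores the caller's `.Random.seed`;
  `run_pipeline()` writes a manifest of parameter values and input/output
  MD5 checksums and is bit-identical across reruns with the same seed.

## Problem sizes in the test suite

Tests run on synthetic instances sized for sharp assertions: oracle
equivalence on ≤ 20 genes × ≤ 10 samples over 20 seeds against a
hand-coded brute-force implementation; recovery on 82-sample atlases with
3 modules × 5 planted regulators and 100 background genes; the
candidate-count bound on 44 bait modules (632 genes); gate calibration on
200–1000 simulation replicates with 4 biological replicates each. These
sizes keep the suite to well under a minute while leaving every claim
assertable exactly or within pre-stated simulation bounds.

## Known limitations

- Pearson/Spearman capture pairwise, roughly monotone co-expression;
  regulators acting condition-specifically or combinatorially can sit far
  down a bait's ranking and below the cap.
- The candidate list inherits the regulator annotation's blind spots:
  an unannotated TF can never be selected.
- The greedy grouping optimizes nothing globally; it is a deterministic
  convention, and different valid conventions yield different (equally
  defensible) partitions.
- The gate's strict thresholds make borderline biology (exactly 2-fold
  induction) a non-hit by definition; follow-up assays, not the gate, are
  the arbiter there.
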