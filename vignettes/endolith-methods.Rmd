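---
title: "Methods: multi-marker metabarcoding and endolithic-trait evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-marker metabarcoding and endolithic-trait evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and parameter choices behind
`endolith`, in the spirit of a methods section: what each stage assumes,
which knobs matter, and what the synthetic-data tests do and do not
demonstrate about real data.

## The library design and what the pipeline assumes

Each sample is sequenced as one pooled library containing four amplicons
(16S, 18S, 23S rDNA, *tufA*).  Samples are separated by the sequencer via
dual indices; markers are separated in software by their primer sequences.
`design_index_oligos()` formalises the cost argument: dual indexing needs
`a + b` oligos to address `a × b` samples (minimised subject to
`a·b ≥ n`, ties to the most square design), against one forward oligo per
sample-marker combination for single indexing.  For 96 samples and 4
markers that is 20 versus 384 (+4 reverse) oligos.

Reads are 2 × 300 nt.  Each first-PCR oligo carries, 5′ of the primer, a
0–3-nt random heterogeneity spacer (to desynchronise base composition
across cycles) and a 33-nt overhang tail.  Two structural consequences
drive pipeline steps 1 and 6:

* A read begins `spacer · primer · insert…`, so primer recognition scans
  spacer offsets 0–3 (`match_primer()`, IUPAC-aware Hamming distance,
  fewest mismatches first, then the smallest offset).
* When the amplicon is shorter than the read, the read continues past the
  insert into the reverse complement of the *opposite* primer and tail.
  `strip_readthrough()` looks for rc(tail·primer) — which appears in read
  orientation as rc(primer)·rc(tail) — at or after position 30 (0-based;
  spacer + primer can never legitimately match earlier) and truncates at
  the match start.  This removes the opposite primer copy from each mate;
  merging restores it from the other mate, so global primer trimming after
  merging still requires and removes both primers.  Truncated tail
  occurrences at the read end are matched down to 12 bases of overlap.

Assignment requires the forward primer on read 1 *and* the reverse primer
on read 2 (conflicting or absent evidence goes to `unassigned`): a
deliberately conservative rule, consistent with the pipeline's general
bias toward under- rather than over-estimation.  The default mismatch
tolerance is 2 per primer; pairwise primer distances are validated at load
time to exceed twice that tolerance, otherwise markers would be
confusable.

## Read preparation

* **3′ trimming** drops a fixed 50 nt from each 300-nt mate (a
  config knob; reads that would fall below 30 nt are dropped).  The study
  design motivates this as removing the lowest-quality cycles before
  merging; the exact extent is not critical because merging re-covers the
  trimmed region from the other mate.
* **Merging** reverse-complements read 2 and scores every suffix–prefix
  overlap of ≥ 10 nt, choosing the smallest mismatch ratio (ties to the
  longest overlap) and rejecting pairs whose best ratio exceeds 0.25 —
  the published defaults of the classic overlap-merging tools.  The
  consensus takes the higher-quality base; consensus quality is max(Q) at
  agreements and |Q1 − Q2| at disagreements (capped at 41).  Equal-quality
  disagreements take read 1's base.
* **Quality filter**: keep merged sequences with arithmetic mean Phred
  ≥ 35, inclusive.  The threshold is interpreted on the Phred scale (not
  the error-probability scale) because that is the natural reading of an
  "average quality of 35".
* **Global primer trim**: the forward primer must sit at the 5′ end (behind
  ≤ 3 spacer bases) and rc(reverse primer) at the 3′ end (before ≤ 3
  trailing bases, the mate's spacer); both copies and spacers are removed
  and a per-marker minimum core length (default 100 nt) enforced.
* Headers become `<sample>.<run>_<serial>`, so `.` and `_` are reserved.

## OTU clustering and chimera screening

Identity is defined by global (Needleman–Wunsch/Gotoh) alignment — match
+1, mismatch −1, gap open −2, gap extension −1 — as matched columns over
alignment columns *excluding terminal-gap columns*; internal gaps count
against identity.  This is stable under ragged amplicon ends while still
penalising indels.  Alignment ties are broken deterministically
(substitution over gap) so that the value is reproducible and can be
checked *exactly* against an independent dynamic-programming oracle; the
tie convention is part of the definition.  The aligner is Rcpp because it
sits in the inner loop of clustering and read mapping.

Clustering is the greedy centroid scheme: dereplicate (exact grouping,
abundance-descending, lexicographic ties), scan uniques in order, assign
to the best centroid at ≥ 98% (*tufA*) / 97% (others) identity — ties
prefer the larger, then the earlier centroid — otherwise screen for
chimeras, and promote clean uniques to new centroids.  Centroids are never
re-centred, which keeps output order-stable and deterministic.  Reads are
then mapped back at the marker's clustering threshold to build the
OTU × sample table; sub-threshold reads are counted `unmapped`.

The chimera screen follows the de novo two-parent model: candidate parents
are centroids with ≥ 2× the query's abundance; the query is chimeric if
some breakpoint (≥ 50 nt from each end) splits it into a left segment
≥ 99% identical to one parent and a right segment ≥ 99% identical to a
different parent, while no single centroid reaches > 97% over the whole
query.  Because parents agree at many positions around the true junction,
the breakpoint is only identified up to a plateau; the reported breakpoint
is the plateau midpoint, which lands within a few bases of planted
junctions.

## Naive Bayes taxonomy with bootstrap confidence

Training counts 8-mers as presence/absence per sequence.  With `n(w)` of
`N` corpus sequences containing word `w`, the prior is
`Pr(w) = (n(w)+0.5)/(N+1)`; with `m(w)` of `M` genus sequences containing
it, the genus-conditional probability is `(m(w)+Pr(w))/(M+1)`.  A query is
scored by the sum of log word probabilities over its word set; 100
bootstrap trials re-score a uniform subsample of ⌈W/8⌉ words (with
replacement) and vote; the confidence of each rank of the winning lineage
is the fraction of votes agreeing at that rank.  These constants (k = 8,
100 trials, 1/8 subsampling) are the classic published values for this
classifier family and are config-exposed.  Confidence is non-increasing
from domain to genus by construction when lineage labels nest; a final
cummax enforces it against degenerate label reuse.  Ranks below the 0.7
reporting threshold render as `unclassified_<deepest confident label>`.

## The three-tier OTU filter

Order is fixed and part of the contract: (i) any OTU with ≥ 1 read in any
negative control is removed *globally* (not subtracted) and control
columns dropped; (ii) cells that do not exceed 2 reads are zeroed and
all-zero rows dropped; (iii) OTUs whose total does not exceed 5 reads are
dropped.  "Exceed" is read strictly (`> n`) following the more explicit of
the two phrasings in the source protocol; an inclusive flag is available.
A regression test pins the order, because swapping (ii) and (iii) changes
results on tables where a zeroed cell decides the dataset-wide sum.

## The Mk model and stochastic mapping

The coral-endolithic character is binary (0 = non-endolithic,
1 = endolithic) and evolves under a continuous-time Markov chain with gain
rate `q01` and loss rate `q10` per million years.  The 2×2 transition
matrix has the closed form with relaxation rate `r = q01+q10`; tip
likelihoods come from Felsenstein pruning with per-node rescaling, checked
exactly against exhaustive enumeration over internal-state assignments on
trees up to 8 tips.  `fit_mk()` maximises the likelihood on the log-rate
scale (Brent search in [e−18, e8] for equal rates; L-BFGS-B for
all-rates-different).  Defaults are the equal-rates variant with the
stationary root prior; monomorphic data return the zero-rate boundary
with a warning rather than silently.

Stochastic maps are drawn exactly: node states are sampled jointly (root
from prior × partial, each child from `P(t)[parent,·] × partial`), then
each branch history is drawn from the chain conditioned on its endpoint
states by uniformization — the number of uniformized jumps from its exact
conditional distribution, jump states by a forward-filtering chain walk,
jump times i.i.d. uniform — which has no discretisation error.  Origins
per map are the number of 0→1 events plus one if the root segment starts
endolithic (the root lineage acquired the state before the crown); this
counting rule is pinned by tests.  Averaging node states over maps gives
the per-node probability of being endolithic, which converges to the
analytic pruning marginals.

Two statistical conventions in the calibration tests deserve note.  The
map-vs-marginal comparison uses a 3σ binomial z-statistic restricted to
nodes where the rarer state has ≥ 5 expected occurrences — on
near-degenerate nodes (marginal ≈ 1 − 10⁻⁵) the normal approximation
fails and a single deviant map inflates |z| far beyond its exact binomial
significance.  The acceptance script summarises the same comparison as the
root-mean-square z over valid nodes (≈ 1 for an exactly calibrated
sampler), because the maximum of ~30 correlated, skewed z-statistics
exceeds any fixed cut on some seeds without indicating bias.  Rate recovery from data simulated at q = 0.05 on 300-tip
trees is assessed as the *median* relative error across 20 replicate
simulations: each replicate is one stochastic realisation, and ML theory
bounds the estimator's spread, not any single draw.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes:
reference genera with independent amplicon cores (between-genus identity
far below the clustering thresholds; within-genus 1% mutants, ≥ 97%),
full amplicons carrying concrete primer sites; multinomial template draws
from community profiles; per-read 0–3-nt spacers; read-through into
rc(primer)·rc(tail)·adapter on short amplicons (the 16S core is 180 nt
precisely so that 300-nt reads read through); linear Phred decay from 38
at 0.02/base (floor 2); substitution errors placed with probability
`substitution_rate × 10^(−Q/10)/mean(10^(−Q/10))` so the quality profile
shapes error placement while the rate sets the total and zero disables
errors exactly; two-parent chimeras with a uniform breakpoint ≥ 50 nt from
the ends; and 5 contaminant pairs per marker injected into negative
controls, drawn uniformly from all taxa.  Defaults: 500 read pairs per
sample per marker (the desk-scale round-trip tests use 300 across
4 markers × 6 samples, and smaller depths where only determinism is at
stake), chimera fraction 1%, substitution rate 10⁻³.

What it does *not* emulate — indels, PCR efficiency bias, index hopping,
overdispersed depth, real reference databases — bounds what green tests
mean: they demonstrate the algorithms are correct against ground truth and
their own invariants, not that real coral-skeleton data are this clean.
The headline numbers of a full-scale survey (millions of retained reads,
thousands of OTUs) require the original sequence archive and curated
references and are out of desk-scale scope.

## Determinism

Every generator and every stochastic stage takes a seed; a single global
seed fans out to stages by stable string hashing (`derive_seed()`), so a
pipeline rerun is byte-identical file by file, and any one stage can be
reproduced in isolation.  All derived seeds stay below 2³¹.

## Known limitations

* The greedy clustering is order-dependent by design (abundance ranking is
  part of the algorithm); it is not an optimal partition.
* The chimera screen models two parents and one breakpoint only.
* `fit_mk` handles one binary character; no rate heterogeneity across
  branches, no correlated characters, no tree inference or dating — trees
  and trait tables are inputs.
* The classifier assumes nested lineage labels and benefits from separated
  genera; confidence on closely related genera degrades as expected.
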