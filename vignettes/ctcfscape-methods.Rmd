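---
title: "Models and methods behind ctcfscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcfscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcfscape)
```

`ctcfscape` identifies CTCF binding sites that are specifically lost or
gained in a cancer type relative to a large cross-tissue ChIP-seq
compendium, and characterizes the calls with chromatin-interaction,
domain, methylation, mutation/motif and TF-enrichment analyses. This
vignette explains the models, the parameters that matter, the numerical
decisions, and what the synthetic benchmark does and does not establish.

## The union atlas and the occupancy model

Peak calls from different datasets rarely agree on boundaries, so the atlas
is built from summits: every peak becomes a window of ±75 bp around its
summit and overlapping windows are merged transitively per chromosome. The
150-bp window width corresponds to the inflection observed in the
distribution of gaps between adjacent pooled summits
(`summit_interval_histogram()` computes this diagnostic): gaps below that
scale reflect the same site measured in different datasets, gaps above it
distinct sites. Merged sites can exceed 150 bp — the envelope of the merged
windows is kept, because truncating it would detach summits from their own
site.

Occupancy counts **datasets, not peaks**: a dataset with two summits inside
one site contributes 1. This makes the occupancy score a cross-dataset
reproducibility tally, bounded by the number of datasets, with the exact
conservation identity that the scores sum to the number of distinct
(dataset, site) incidences. Sites with score ≥ 3
(`high_confidence_min_occupancy`) are retained for calling; singletons and
doubletons are dominated by dataset-specific noise.

Dataset-level filters mirror standard ChIP-seq practice: peaks with fold
enrichment < 4 are dropped, and a dataset retaining fewer than
`min_peaks_per_dataset` peaks (2000 at compendium scale) is excluded rather
than allowed to dilute occupancy frequencies. Desk-scale scenario manifests
carry a proportionally scaled-down value of this filter, since a synthetic
chromosome cannot host thousands of peaks.

A narrowPeak summit offset of −1 means "unknown"; the reader falls back to
the interval midpoint and warns, rather than discarding the record or
inventing an error.

## The constitutive-site cutoff

The occupancy-score distribution of a large compendium is heavy-tailed:
most sites appear in few datasets, but a distinct population is bound
nearly everywhere. The bulk is modeled as a shifted power law
`E_i = a (i − b)^(−c)`, fit by least squares of `log O_i` on `log(i − b)`
with the offset `b` found by bounded one-dimensional search on
`[0, min(fit range) − 0.01]`. Log-space least squares is deliberately
chosen over direct nonlinear fitting: counts span orders of magnitude, and
log-space weighting keeps the abundant low-occupancy scores from dominating
the exponent.

The constitutive cutoff is the smallest score `A` whose observed tail
exceeds the model more than `excess_factor = 5` times:

$$A = \min\left\{ i \;:\; \frac{\sum_{j \ge i} (O_j - E_j)}{\sum_{j \ge i} E_j} > 5 \right\}$$

i.e. the observed tail is more than six-fold the expected tail.
Constitutive sites are those with score **≥ A + 1**. When no score
qualifies, `A` is absent (a valid outcome, not an error) and the fallback
is the frequency rule, score ≥ ⌈0.8 × n datasets⌉. The two rules disagree
by rounding at compendium scale; the empirical-model cutoff is primary
because it adapts to the data, and the rule that fired is recorded on the
result. `determine_cutoff()` is monotone in the excess factor by
construction.

## Calling cancer-specific sites

Binding levels are RPKM quantile-normalized across datasets (tie handling:
tied ranks receive the mean of the reference values at those ranks).
Differential binding is an unpaired two-tailed **pooled-variance** Student
t test — pooled rather than Welch to match the classical test the name
denotes; a Welch variant would be a one-line change but would alter the
calling behavior, so it is not silently offered. Effect size is Cohen's d
with the pooled SD. Benjamini–Hochberg adjustment is applied per comparison
family: all tested sites of one cancer type for one comparison
(vs-all-others and vs-matched-normal are separate families). Degenerate
inputs are explicit: zero pooled variance with equal means gives t = 0,
p = 1; with unequal means the site is flagged `degenerate` with p recorded
as 0.

The lost and gained definitions are conjunctions over occupancy strata and
binding levels (see `call_cancer_specific_sites()`), and they are
deliberately asymmetric: lost sites require only the *sign* of the t
statistic (a site absent from a cancer has little signal variance to test),
while gained sites require FDR ≤ 0.01 — a gain claim rests on strong
statistical evidence of elevated binding. The gained FDR criteria
additionally require t > 0, making "significantly higher" directional; a
two-tailed FDR alone would also pass significantly *lower* sites. The
mutual exclusivity of the two calls is structural: overall frequency cannot
be both ≥ 0.7 and ≤ 0.2. Every criterion's outcome is a ledger column in
the output, so a "none" call is always attributable to the specific
criterion that failed.

The "all other datasets" stratum excludes only the cancer type's own
datasets (matched normals stay in): excluding them too would remove the
tissue background that the matched-normal criteria are designed to control
separately.

## Chromatin domains and target genes

A site's chromatin domain is bounded on each side by the nearest
constitutive site whose distance from the anchor is between
`domain_min_side` = 100 kb and `domain_max_side` = 1 Mb and whose motif
orientation fits the configured rule. The default rule is **divergent**
(left boundary on the minus strand, right on plus), the orientation under
which boundary motifs point away from the interior as loop-extrusion
models predict for domain boundaries; `convergent` and `opposite_any` are
available and the mode is reported in output metadata. The per-side
bounds are interpreted per side (not as total width): each side
independently spans 100 kb–1 Mb. Constitutive sites failing orientation or
the minimum distance are skipped, not treated as blockers — with no
evidence on intervening sites' insulating role, skipping is the weaker
assumption. In `opposite_any` mode the qualifying pair with the smallest
total span wins, ties to the nearer left boundary.

Candidate target genes follow a promoter-first precedence: if the site
overlaps any TSS ± 2 kb, those genes are its promoter targets and domain
membership is not consulted; otherwise every gene whose **TSS** (not gene
body) lies in the domain is an intra-domain target. The three categories
partition all same-chromosome site–gene pairs.

CTCF–gene association is the Pearson correlation of square-root RPKM
(quantile normalized across cell types) against square-root TPM; a pair is
highly correlated iff R² **strictly** exceeds 0.25. Zero-variance vectors
make r undefined; such pairs are flagged and never counted as highly
correlated. Differential-expression enrichment uses the two-tailed
Fisher's exact test with the minimum-likelihood convention (sum of
hypergeometric probabilities ≤ the observed table's, with a 1 + 1e-7
relative guard against floating-point ties); 0.5 is added to the table
cells only when a margin is zero, and then flagged.

## Hi-C normalization and differential interaction

Contact maps are symmetric sparse bin-pair sets (5-kb bins). Because
contact probability decays with genomic distance, each entry is divided by
the chromosome-wide mean count at its distance, zeros included in the mean;
after normalization the mean at every distance is exactly 1. Distances
with zero total count stay zero and are excluded from downstream vectors;
the diagonal is excluded entirely. No matrix balancing (ICE/KR) is
applied — the normalization is expected-at-distance only, so raw and
normalized values remain proportional within a distance stratum.

Differential interaction at a site pairs the normalized interactions
between the site's anchor bin and every bin within `hic_flank_L` = 500 kb
on **both** sides (the one-sided variant is available via `sides`), then
applies a paired two-tailed t test to the differences. Log2 fold changes
use a pseudocount of 0.01 on normalized values, which are O(1) by
construction, so the pseudocount only guards true zeros without distorting
typical entries. Intra-domain differentially interacting regions require
both |log2 FC| > 1 and a positive mean log2 interaction across the two
conditions — the second condition keeps noise-level bins with large
relative but negligible absolute change out of the TF-enrichment input.

## Methylation and mutation models

Differential methylation is deliberately simple: the mean per-CpG
difference (cancer − normal, percentage points) over the 300-bp window
centered on the site, using only CpGs covered ≥ 5× at the same position in
both conditions, requiring ≥ 3 such CpGs, with |Δ| strictly > 20 calling
hyper/hypo. No beta-binomial shrinkage or smoothing is applied — the
hard-threshold rule keeps each call auditable. The genome-wide association
profile ranks sites by their differential-binding t statistic into 100
equal-count bins (remainder to the first bins) and stacks per-bin status
fractions; anti-correlation between median t and the hyper fraction is the
signature of methylation gain accompanying binding loss.

Mutation profiles count events per (sample, position) at each offset of
the 400-bp window around site centers, divided by the number of sites.
Motif disruption scores the 19-bp PWM window on the annotated strand for
the reference and alternate alleles; the delta is antisymmetric by
construction and indels are profiled but not motif-scored.

## PWM scanning and exact p-values

PFM counts receive a 0.5 pseudocount per cell before conversion to
probabilities, avoiding −∞ log-ratios for zero counts; scores are log2
likelihood ratios against the background (0.275, 0.225, 0.225, 0.275). The
null distribution of the total score of a random background sequence is
computed by dynamic programming over per-position score distributions: for
matrices up to width 11 the achievable sums are carried exactly
(value-merged convolution), wider matrices use a lattice with step 1e-3
log-units. Tail p-values use a 1e-9 score tolerance so that a score
actually achieved by a sequence always includes that sequence's mass — the
p-value is monotone non-increasing and equals 1 at −∞.

Site scanning evaluates every window on both strands, skips windows with
non-ACGT bases (warning), keeps hits with p ≤ 1e-4, and retains the single
smallest-p hit; ties break to the smaller start, then the plus strand — an
arbitrary but fixed rule, recorded here because any tie-break is defensible
and only determinism matters.

## The synthetic benchmark: what it emulates, and what it does not

`generate_scenario()` plants five site classes on two 2-Mb chromosomes with
per-cohort peak presence probabilities (constitutive 0.95 everywhere;
common 0.85; lost 0.02 in cancer / 0.95 elsewhere; gained 0.95 in cancer,
absent elsewhere; sample-specific 0.05), 8 cancer + 8 matched-normal + 24
other datasets, and 50 planted lost + 50 gained among 2,000 sites. Gained
sites are planted with the same within-cancer consistency as constitutive
sites show in their cohorts: a gained call requires presence in ≥ 50% of
cancer datasets plus FDR-level signal evidence, so the planted class must
be a consistently bound one for its margins to be recoverable at all.

Signal is log-normal RPKM, `2^(−1 + 3.3·bound + N(0, 0.3))`: unbound
background ≈ 0.5 RPKM and a ~10-fold bound/unbound ratio, consistent with
the generator's own ≥ 4 fold-enrichment peak model, with 0.3 log2 units of
replicate-grade within-cohort noise. Contact maps decay as `d^(−1)` with
Poisson counts and a 2× planted boost within 500 kb of gained anchors;
methylation is binomial per CpG at 30% baseline, +30 points at lost sites
and −30 at gained sites in cancer (anti-correlated with the planted
binding change), with Poisson(50) coverage and 10% of sites emitted
low-coverage to exercise the insufficiency filter; mutations are uniform
Poisson background at 1e-4 per bp per sample. Each modality draws from its
own keyed substream of the scenario seed, so adding one modality never
perturbs another, and everything is byte-reproducible from the seed.

What the generator does **not** emulate: peak-boundary irregularity beyond
summit jitter, batch structure or lab effects in signal, fragment-level
Hi-C artifacts (so no balancing is needed or tested), CpG-island coverage
bias of real RRBS, mutational signatures, or realistic chromatin-state
segmentation. Passing the benchmark therefore establishes the
*correctness* of each stage's computation and the *internal consistency*
of the criteria under idealized noise — not performance on real compendium
data, where cross-dataset heterogeneity is substantially larger.

Problem sizes in the test suite are chosen for desk-scale turnaround: the
end-to-end benchmark uses the default 2,000-site scenario; Hi-C
calibration uses 1,000 null anchors over ten 200-bin map pairs; the
binding–methylation association uses a 1,200-site scenario with the lost
fraction raised to 15% so the 100-bin profile has planted signal across
many bins rather than only its extreme tail; exhaustive oracles (Fisher
tables to total 60, PWM enumeration to width 8, 1,000 domain instances)
run at the sizes where enumeration is exact and fast.

## Known limitations

* The power-law fit leaves the fitting range to the caller; on occupancy
  distributions that are not power-law-shaped (e.g. cohort-structured
  mixtures like the synthetic scenario's), the cutoff can be meaningless —
  the benchmark therefore evaluates it on its own generative model.
* The caller assumes one matched-normal stratum per cancer type and ≥ 2
  datasets per group; calls are disabled, with an explicit error, when the
  matched-normal stratum is missing.
* Quantile normalization assumes comparable global signal distributions
  across datasets; it cannot correct antibody-efficiency differences that
  alter the bound/unbound mixture itself.
* TF enrichment implements the Fisher ranking over a user-supplied
  repertoire and binary profiles; corpus curation is out of scope.
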