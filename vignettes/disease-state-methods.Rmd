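---
title: "Methods: snapshot clustering, stability selection, and progression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot clustering, stability selection, and progression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snapstate)
```

`snapstate` turns long-format complaint mentions — one row per NLP-extracted
clinical concept, with patient, timestamp, and polarity — into a set of
data-driven disease states, their hierarchy, their clinical profile, and a
temporal network of progression between them. This vignette records the
model, its assumptions, the tunable parameters, and the design decisions
taken where reasonable alternatives existed.

## The snapshot representation

The analysis unit is the *snapshot*: all positive-polarity mentions of one
patient inside one half-open 30-day window, `[start, start + 30)` days,
anchored at the patient's first mention and indexed from 0. Thirty days is a
clinically meaningful resolution for a condition whose presentation can
change month to month; the width is a parameter (`bin_width`) for other
cadences. Negated mentions are removed first — "no evidence of heart
failure" tells us what the patient does *not* have. Bins without mentions
simply do not exist as snapshots; downstream stages must and do tolerate
such gaps.

Two cohort-hygiene rules precede vectorization, both from the reference
workflow and both configurable:

* **Exclusion** (`min_mentions = 10`): any patient with at least one
  snapshot under 10 mentions is removed entirely. The rule is patient-level
  because sparse snapshots signal unreliable documentation for that patient
  as a whole; a snapshot-level drop mode exists (`mode = "snapshot"`).
* **Vocabulary truncation** (`coverage = 0.99`): complaint frequencies in
  clinical text follow a power law, so a small head of the vocabulary
  carries nearly all mentions. We read "99% most frequent complaints" as the
  smallest most-frequent prefix covering 99% of cumulative mention mass
  (ties broken lexicographically for determinism). This reading is
  consistent with the large vocabulary reductions seen on power-law data; a
  per-concept rank-quantile alternative is available
  (`method = "rank"`).

Snapshots are vectorized with sublinear TF and smoothed IDF,

$$tf(c) = 1 + \ln(\mathrm{count}), \qquad
  idf(c) = \ln\frac{1+N}{1+df(c)} + 1,$$

then each row is scaled to unit L2 norm. The log term frequency damps the
templated, copy-pasted text that inflates raw counts in clinical notes; the
L2 normalization makes snapshots with different documentation volumes
comparable. Rows whose every concept fell outside the truncated vocabulary
cannot be normalized and are dropped with a warning. One upstream ambiguity
deserves note: the source analysis describes per-patient aggregation in one
place and snapshot-level clustering (N = 103,833 snapshots) in another; this
package clusters snapshots, the reading consistent with every downstream
stage (per-snapshot labels, per-snapshot event flags).

## State discovery and stability selection

K-means (Lloyd iterations, k-means++ seeding, 10 restarts keeping the best
within-cluster sum of squares) partitions the rows for each K in
`k_range = 2:30`. On unit-norm vectors squared Euclidean distance is a
monotone transform of cosine distance, so no separate cosine implementation
is needed. Restart counts and all seeds are explicit; a run is reproducible
bit-for-bit.

There is no single "true" K; instead K values are kept when the partition is
*stable under subsampling*. For each K and each fraction `f_d` in the
geometric schedule `0.5, 0.25, ..., 0.0078125`, we repeatedly (default
`n_reps = 1000`; reducible) draw `floor(f_d N)` rows without replacement,
re-cluster, and compare against the reference partition restricted to the
sampled rows via the data-point-weighted Jaccard statistic

$$J = \frac{1}{N}\sum_i\sum_j n_{ij} J_{ij}, \qquad
  J_{ij} = \frac{|c_i^{ref} \cap c_j^{boot}|}{|c_i^{ref} \cup c_j^{boot}|}.$$

Restricting the reference to the subsample is the only way the
cross-counts $n_{ij}$ are well defined; sampling is without replacement
("subsampling a fixed fraction"). No explicit cluster matching is needed —
the double sum ranges over all pairs. A semantic analogue $S$ replaces the
set overlap of *points* with the overlap of each cluster's significantly
enriched complaint vocabulary, $S_{ij} = |v_i^{ref} \cap v_j^{boot}| /
|v_j^{boot}|$; a bootstrap cluster with an empty significant vocabulary
contributes 0 (no evidence of agreement). Computing $S$ requires a full
significance battery per replicate, so it is opt-in
(`compute_semantic = TRUE`).

**Stable K** = strict local maxima of mean $J$ over the K grid at
`f_d = 0.5`, endpoints compared one-sidedly. The mean over replicates is the
default summary (median switchable); a `strict` mode additionally requires
an $S$ maximum and persistence of the $J$ maximum across smaller fractions —
the default is J-only because the stricter conjunction is ambiguous in the
source description and markedly more expensive. The finest stable K defines
the reported disease states.

The hierarchy over the finest-K clusters is built from the coarser stable
partitions: for each coarser stable K the finest clusters' Jaccard profiles
against the coarse clusters are computed, Euclidean distances between
profiles are averaged across all coarser K, and complete-linkage
agglomeration gives a binary dendrogram whose merges are annotated with the
smallest stable K separating the two branches.

## State characterization

Distinctive complaints per state come from one-sided (greater) tests of each
feature's TF-IDF values inside the cluster versus all other snapshots, with
Bonferroni correction over the feature battery. The default test is the
Mann–Whitney rank-sum: sparse TF-IDF columns are zero-inflated and far from
normal, and the source's own tabulated results use a rank-sum test even
though its prose mentions a t-test; a one-sided Welch t-test is available
(`method = "ttest"`). The implementation vectorises the normal approximation
with tie correction and continuity correction — the same large-sample path
`wilcox.test` takes under ties, verified against it in the test suite.
Constant features receive p = 1 rather than an error. The Bonferroni family
defaults to one cluster's battery (|V| tests), re-run per cluster; a global
|V| x K family is available.

Phenotype grouping is deliberately simple: case-insensitive substring
matching of curated keywords against concept display strings, first-declared
phenotype winning on overlaps, so the mapping is deterministic given map
order. The bundled 50-phenotype map is an illustrative example of the format
(`phenotype, keyword`), not a clinically validated instrument; real analyses
should supply their own. Enrichment per (state, phenotype) uses the 2x2
in-cluster x phenotype-present table with a Haldane–Anscombe 0.5 correction
on zero cells. Clinical summaries cap ages at 32,872 days (90 years) for
de-identification comparability, use the age at which the patient first
enters the snapshot, average BMI measurements within the 30-day window (and
report the fraction of snapshots contributing), and take % female and
in-hospital mortality from the demographics/event tables.

## Event risk

For each event type, a snapshot is *present-labelled* when an event
timestamp falls inside its window (events are binned with the same
per-patient anchoring as mentions), and *pre-event-labelled* when it
strictly precedes the patient's first event-containing snapshot. "Future
risk" therefore means risk before first occurrence — the stricter of the two
readings; before-any-occurrence is a configuration alternative not needed by
any consumer in this package. Per-state prevalences use snapshot-level
denominators, consistent with the snapshot-level density overlays;
patient-level denominators would answer a different (also legitimate)
question. Kernel density overlays over a 2D embedding use Gaussian kernels
with Scott's-rule bandwidths per axis and are normalized to integrate to 1.

The 2D embedding (`embed_2d`) is the first two principal components of the
TF-IDF matrix: deterministic, fast, and adequate for map-style figures and
density overlays, which carry no quantitative claims in this package.

## The progression network

Temporal structure is estimated pairwise at the patient level:

1. **Association.** For each unordered state pair, patients are
   cross-classified by whether each state appears anywhere in their
   timeline; $OR_{ij} = (n_{ij} n_{\neg i \neg j})/(n_{i\neg j} n_{\neg i j})$
   with a 0.5 correction on zero cells (logged) and a Wald 95% CI on the log
   odds ratio. A pair is significant when the CI excludes 1 — the masking
   criterion; the CI method is Wald because no specific interval is
   prescribed by the source. Pair tests are uncorrected by default (the
   reference analysis reports none); Bonferroni across the K(K-1)/2 pairs is
   a switch.
2. **Ordering.** Among patients with both states, the fraction whose
   *first occurrence* of i precedes j gives $p_{ij}$; with one state per
   snapshot, first occurrences cannot tie, so $p_{ij} + p_{ji} = 1$. Median
   transition times count 30-day bins of calendar time (gaps included), the
   natural clock for "how long until the next state".

Edges are significant pairs with OR above 1.33; direction follows $p_{ij}$
with the band [0.45, 0.55] rendered bidirectional; bidirectional edges carry
the mean of the two directional medians. Start (end) states have only
outgoing (incoming) arrows, a bidirectional arrow counting as both.

An estimand subtlety: pairwise co-occurrence plus first-occurrence ordering
detects *ancestor–descendant* temporal association, not adjacent Markov
transitions — if patients flow 1 → 2 → 3, the pair (1, 3) is genuinely
co-occurring and ordered, and an edge 1 → 3 is a correct finding of this
method, not a false positive. The synthetic generator therefore records both
the directly planted edges and their ordered reachability closure
(`progression_pairs`), and recovery is scored against the closure.

## The synthetic cohort generator

Real mention-level EHR data of this kind are available only under data-use
agreements, so the generator is a first-class module that plants everything
the pipeline claims to find:

* **Vocabulary**: background complaint frequencies Zipf-distributed
  (`zipf_exponent = 1.5`, a typical clinical-text exponent) over
  `vocab_size = 500` concepts.
* **States**: `n_states = 4` by default, each enriching 8 dedicated
  signature complaints by `signature_lift = 20` over background. Sibling
  states under the same parent group share an additional parent-level
  signature block (`parent_lift`, default equal to the state lift), which is
  what the dendrogram stage recovers. State signatures occupy better
  frequency ranks than the parent blocks so each state's own signal
  dominates its group signal; with both lifts at 20, K-means recovers both
  the 4 planted states (ARI ≈ 0.96) and the 2 parent groups.
* **Dynamics**: a Markov chain per patient over a row-stochastic transition
  matrix (default: a forward chain with self-transition 0.5, i.e. geometric
  dwell with mean 2 bins, absorbing final state); timeline lengths from
  `1 + Geometric(1/5)` capped at 30 bins, giving a median near 4 bins with a
  long right tail, echoing routinely collected EHR timelines.
* **Observation**: Poisson(25) mentions per bin, 5% of bins forced empty to
  exercise gap handling, 10% of mentions flagged negative polarity; events
  per bin are Bernoulli with per-state rates; demographics (age, sex, BMI)
  drawn per state.
* **Study conditions**: cohorts of `n_patients = 2000` by default — the
  scale at which the recovery checks (stable-K selection, ARI ≥ 0.9,
  network precision/recall ≥ 0.8) are run.

What the generator does *not* emulate: free-text notes and NER errors,
concept-normalization noise, multimorbid snapshots (one true state per
snapshot; multimorbidity is expressed through mixture overlap), non-
stationary documentation practices, and informative observation gaps. A
passing recovery suite therefore demonstrates the pipeline's correctness and
statistical behaviour under its own assumptions, not robustness to the many
ways real EHR data violate them.

## Numerical choices and degenerate inputs

* k-means: Lloyd with k-means++ seeding; 10 restarts for reference runs, 2
  for bootstrap replicates (enough to avoid the worst local optima without
  dominating runtime); degenerate empty-cluster solutions are retried with a
  fresh seeding.
* Vocabulary truncation breaks count ties lexicographically; the truncation
  is computed after cohort exclusion (the order is unstated upstream; after
  is self-consistent — excluded patients contribute no mass).
* `J` and `S` are exact finite-sample statistics, no approximation; the
  rank-sum test uses the tie-corrected normal approximation with continuity
  correction.
* Odds ratios: 0.5 added to all four cells whenever any is zero, flagged in
  the output.
* Subsample cells smaller than K are skipped with a warning; an empty edge
  set yields a valid network of isolated nodes.
* Every stochastic step takes an explicit seed; per-replicate seeds are
  drawn up front from the master seed, so profiles are reproducible and
  individual replicates re-runnable.

## Problem sizes used by the test suite

The packaged tests run at desk scale, chosen once: unit tests on cohorts of
200–800 patients; recovery checks at 2,000 patients, 100 bootstrap
replicates at `f_d = 0.5` over K = 2..7; calibration checks with 1,000
label permutations (family-wise error of the Bonferroni battery) and 60
independent-state replicates (nominal 5% false-flag rate of the CI mask);
the stability-decay trend at 800 patients, 50 replicates across the full
`f_d` schedule, assessed with a one-sided Kendall trend test. The
paper-scale defaults (K up to 30, 1,000 replicates) remain the package
defaults and are reduced explicitly in test and script configurations.

## Limitations

Pairwise ordering cannot represent higher-order trajectories; hard
assignment hides within-snapshot mixtures; the stability criterion favours
K values whose partitions are re-identifiable under subsampling, which can
prefer coarse solutions when clusters overlap heavily; and all clinical
interpretability of discovered states (naming, phenotype maps) remains a
human task on real data.
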