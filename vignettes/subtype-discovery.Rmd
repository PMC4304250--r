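---
title: "Consensus NMF subtype discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus NMF subtype discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfsubtypes)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) cohorts with the same pathological
stage show widely different clinical courses. Unsupervised molecular
subtyping asks whether bulk expression profiles alone partition a cohort
into groups that differ in survival and clinicopathologic behavior. This
package implements one complete route to that answer: consensus
non-negative matrix factorization (NMF) for the partition, then survival,
association, differential-expression and enrichment stages to characterize
it, all exercised against a synthetic cohort generator with known ground
truth.

## The factorization model

The expression matrix $A$ ($n$ genes $\times$ $m$ samples) is approximated
as $A \approx WH$ with $W$ ($n \times k$) and $H$ ($k \times m$)
non-negative; the $k$ columns of $W$ are metagenes and each column of $H$
gives a sample's metagene weights. The fit minimizes the
Kullback–Leibler-type divergence

$$D(A\,\|\,WH) = \sum_{ij}\Big(A_{ij}\log\frac{A_{ij}}{(WH)_{ij}} -
A_{ij} + (WH)_{ij}\Big),$$

by the classical multiplicative updates, one sweep updating $W$ and then
$H$ with the already-updated $W$:

$$W_{ia} \leftarrow W_{ia}\frac{\sum_u H_{au} A_{iu}/(WH)_{iu}}
{\sum_v H_{av}}, \qquad
H_{au} \leftarrow H_{au}\frac{\sum_i W_{ia} A_{iu}/(WH)_{iu}}
{\sum_k W_{ka}}.$$

Because expression arrives on the log2 scale (which has negative values),
the NMF input is the elementwise exponential scaling $2^x$
(`exponential_scale()`), guaranteeing non-negativity while preserving
ordering.

Numerical choices:

* **Initialization.** $W$ and $H$ start from seeded uniform $(0,1]$ draws
  scaled by $\sqrt{\bar A / k}$, so the initial reconstruction matches the
  data's magnitude and every entry is strictly positive. A fixed seed
  reproduces the factorization bitwise.
* **Epsilon floors.** Denominators (and the log argument in the divergence)
  are floored at $10^{-12}$, so degenerate zero rows or columns cannot
  produce 0/0; the multiplicative form otherwise preserves non-negativity
  exactly.
* **Stopping.** The loop stops at `max_iter = 1000` sweeps, or earlier when
  the sample connectivity pattern (the argmax metagene of each $H$ column)
  has been unchanged for 40 consecutive checks taken every 10 sweeps. This
  connectivity-stability rule is the natural criterion when the
  factorization feeds consensus clustering: what must stabilize is the
  partition, not the last digits of the divergence. For accuracy-critical
  uses (e.g. verifying exact low-rank recovery) the rule can be disabled
  with `conv_check = NULL`.
* **Update order.** $W$ before $H$ within a sweep, using the updated $W$;
  the divergence is non-increasing under either order, and tests assert
  the monotonicity per sweep.

## Consensus clustering and rank selection

A single NMF run depends on its initialization, so the partition is read
from many restarts. For each rank $k$ in the candidate range (default
2–4), `select_rank()` runs `n_runs` seeded restarts; each run yields a
binary connectivity matrix (samples share a dominant metagene or not, ties
to the lowest metagene index), and their elementwise mean is the consensus
matrix — entry $(i,j)$ is the fraction of restarts co-clustering samples
$i$ and $j$.

Stability is scored by the cophenetic correlation coefficient: with
distances $Y = 1 - \text{consensus}$, average-linkage hierarchical
clustering yields dendrogrammatic (cophenetic) distances $Z$, and

$$c = \frac{\sum_{i<j}(Y_{ij}-\bar y)(Z_{ij}-\bar z)}
{\sqrt{\sum_{i<j}(Y_{ij}-\bar y)^2\sum_{i<j}(Z_{ij}-\bar z)^2}}.$$

A perfectly stable consensus is block 0/1, its distances are ultrametric,
and $c = 1$ exactly; instability pushes $c$ down. The selected rank is the
one with maximal $c$ (ties to the smallest rank). An all-constant distance
matrix carries no contradiction with any dendrogram and is defined as
$c = 1$ with a message.

Final subtype labels come from cutting the consensus dendrogram into
$k^\*$ groups rather than from any single run's $H$: the consensus cut is
restart-stable by construction. Labels are renumbered by decreasing
cluster size (subtype 1 = largest), purely a display convention — every
downstream comparison is label-invariant.

Defaults: `n_runs = 30` restarts per rank (20 are used in the heavier
simulation suites; the cophenetic curve is already stable there), rank
range 2–4. Restart seeds are derived as `base_seed + 1000 k + run`, so a
run is reproducible in isolation.

## The synthetic cohort generator

`simulate_cohort()` produces the study structure every stage assumes,
with ground truth attached:

* **Cohort layout.** 96 samples in three subtypes of 43/45/8; 2000 genes.
  Real cohorts carry ~20,000 genes; 2000 keeps simulation suites fast
  while preserving the marker-to-background ratio that drives clustering
  difficulty.
* **Expression.** Baseline Gaussian log2 values, mean 8, sd `noise_sd`
  (default 0.5 — a typical within-group spread for microarray log2
  intensities). Each subtype owns a disjoint random block of
  `markers_per_subtype` genes (default 100, i.e. 5% of the genes per
  signature, the order of magnitude of published subtype signatures)
  shifted up by `marker_log2_shift` (default 2, a four-fold change).
* **Survival.** Exponential times with rate $\ln 2 / \text{median}$ at
  per-subtype medians 37.6/19.2/13.8 months — the single-parameter law
  pinned down by the only published summary (the medians). Censoring is an
  independent uniform follow-up window $U(0, u)$ with $u$ solved
  numerically so the expected censoring fraction matches the configured
  per-subtype rates (27/43, 22/45, 4/8).
* **Covariates.** Bernoulli draws per subtype at the observed rates for R0
  resection, distant metastasis and recurrence.

What the generator does **not** emulate: probe-level microarray structure,
batch effects, gene–gene correlation beyond the planted blocks, competing
risks, or non-exponential survival shapes. Passing the recovery suites
therefore shows the pipeline's machinery is correct and calibrated on data
with clean planted structure — it does not certify performance on real
cohorts, where separation is weaker and noise is structured. Covariates
that the original analyses never reuse downstream (operation type,
chemotherapy agent) are not simulated.

A note on statistical power: with exponential survival at medians 37.6 vs
19.2 months the hazard ratio is 1.96, and with 43 + 45 patients the
two-group log-rank test has roughly 85% power even without censoring
(Schoenfeld's approximation; about 55% at the configured censoring). The
power suite reports exactly this, so a two-group comparison at these
medians should not be expected to clear 90% power under this survival
law; observed significance in real cohorts of this size implies a
stronger-than-exponential separation.

## Survival, association, and the choice of tests

Kaplan–Meier estimation and the log-rank statistics are delegated to the
`survival` package behind small wrappers that fix the conventions: events
precede censorings at tied times; the median is the first time with
$S(t) \le 0.5$ (returned as `NA` when never reached); pairwise subtype
p-values are reported unadjusted, matching the convention of reporting
each pairwise log-rank separately.

The association battery mirrors a clinicopathologic characteristics
table: counts with within-subtype percentages (one decimal), Fisher's
exact test (two-sided, point-probability summation) for 2×2 tables,
Pearson chi-square otherwise, Kruskal–Wallis for continuous-by-group —
each overridable, since the original tables rarely name their tests.
Degenerate tables (a zero margin) are defined as p = 1 with a message
rather than an error, so a battery over many covariates never aborts.

## SAM differential expression

Marker discovery is one-vs-rest: for subtype $g$, each gene gets

$$d_i = \frac{\bar x_{i,\text{case}} - \bar x_{i,\text{rest}}}{s_i + s_0},$$

with $s_i$ the pooled standard error of the mean difference and the fudge
factor $s_0$ defaulting to the median of the $s_i$ — the standard
simplification of the full SAM tuning search, enough to stop
near-zero-variance genes from dominating. FDR comes from `n_perm = 1000`
seeded permutations of the case mask: the q at threshold $|d_i|$ is the
median permuted count of statistics at or above $|d_i|$ over the observed
count, monotonized so larger $|d|$ never has larger q. "q = 0" therefore
means literally no permuted statistic reached the gene's $|d|$ in at least
half the permutations — an estimator-dependent statement, not a
theoretical zero. When fewer distinct case assignments exist than
`n_perm`, all of them are enumerated. Markers are then the top 20 genes at
q = 0 with linear fold change (ratio of $2^x$ means) above 1, ordered by
fold change.

## GSEA

Enrichment between the two largest subtypes (the smallest is excluded —
eight samples cannot support a stable phenotype permutation) uses the
weighted Kolmogorov–Smirnov running sum with weight $p = 1$: walking down
the signal-to-noise-ranked list, hits add $|s|^p$ normalized by the total
hit weight, misses subtract $1/(N - N_h)$, and the enrichment score (ES)
is the signed extremum, always in $[-1, 1]$. The signal-to-noise sd uses
an absolute floor of 0.2 per class. Permutation is over phenotype labels
(not genes), preserving gene–gene correlation; NES divides each ES by the
mean |permuted ES| of the same sign for that set, and FDR q compares each
NES against the pooled permuted NES of its sign. Two degenerate
conventions: a set spanning the whole ranked universe has ES = 0 (its
running sum is defined as identically zero), and sets are size-filtered to
15–500 genes after intersection with the matrix. Note that under
phenotype permutation a planted (internally correlated) set also scores
under the null, so its NES is modest even when its observed ES is 1.0 —
the FDR q, not the NES magnitude, is the reporting quantity, with the
conventional q < 0.25 threshold.

## Problem sizes in the test and acceptance suites

The simulation suites run at the study scale — 96 samples, 2000 genes,
planted 43/45/8, shift 2, noise 0.5, 20 restarts per rank, 20 simulated
cohorts for the rank-selection and label-recovery checks; 1000 null trials
for log-rank calibration; 1000 permutations for the SAM recovery check and
200 for the GSEA check. Module-level tests use smaller fixtures (300–500
genes, 8–10 restarts, slightly stronger separation) chosen to make each
property unambiguous at interactive speed.

## Known limitations

* The exponential survival law and independent uniform censoring are the
  simplest mechanisms matching the published summaries; real follow-up is
  neither memoryless nor uniform.
* The cophenetic criterion compares ranks 2–4 only; a cohort with more
  structure needs a wider range and correspondingly more restarts.
* SAM's $s_0$ is fixed at the median $s_i$ rather than tuned; q-values are
  permutation estimates with granularity $1/n_\text{perm}$.
* Probe-to-gene collapsing of array data is out of scope: the pipeline
  expects an already-collapsed genes × samples matrix.
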