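---
title: "Methods: behavioural profiling and connectome analysis in behavconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural profiling and connectome analysis in behavconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavconn)
```

# Overview

`behavconn` implements a transdiagnostic analysis linking children's
behavioural difficulties to functional brain organisation. The pipeline has
four scientific stages:

1. **Behavioural profiling.** Subjects are clustered by the *shape* of their
   behavioural rating profile (six questionnaire scales as T-scores) using
   consensus community detection on a signed subject-by-subject correlation
   network.
2. **Connectome construction.** Per-subject region-by-region Pearson
   correlation matrices are motion- and outlier-filtered, proportionally
   thresholded at a fixed edge density (cost), and summarised within and
   between eight intrinsic connectivity networks (ICNs).
3. **Graph topology.** Weighted nodal and global graph metrics are computed
   and normalised against random networks that preserve each connectome's
   degree sequence and weight multiset; connector and provincial hubs are
   classified by percentile rules.
4. **Brain-behaviour prediction.** Partial least squares (PLS) regression
   predicts one-hot profile membership from connectivity features, with
   repeated cross-validation, one-standard-error model selection, permutation
   significance, and Procrustes-aligned bootstrap loading stability.

Because the cohorts this kind of analysis is applied to are typically
access-restricted, the package ships a synthetic cohort generator whose
defaults define the study conditions for all tests.

# Behavioural network and consensus communities

For subjects $i, j$ with scale-score vectors $x_i, x_j \in \mathbb{R}^6$, the
network edge is the Pearson correlation $r_{ij} = \mathrm{cor}(x_i, x_j)$
across the six scales. Edges therefore measure similarity of profile *shape*,
not overall severity; subjects whose six scores do not vary are excluded
(their correlation is undefined), and subjects flagged by a Negative
Impressions score above a configurable cutoff can be excluded before network
construction.

Correlations can be negative, so community detection uses the symmetric
signed modularity: with $W^+ = \max(W, 0)$, $W^- = \max(-W, 0)$, total
weights $s^\pm = \sum_{ij} W^\pm_{ij}$ and strengths
$k^\pm_i = \sum_j W^\pm_{ij}$,

$$Q = \frac{1}{s^+ + s^-} \sum_{ij} \left[ \left(W^+_{ij} - \gamma
\frac{k^+_i k^+_j}{s^+}\right) - \left(W^-_{ij} - \gamma \frac{k^-_i
k^-_j}{s^-}\right) \right] \delta(c_i, c_j),$$

the convention the Brain Connectivity Toolbox uses for signed networks.
The resolution $\gamma$ defaults to 1.

`louvainPartition()` maximises $Q$ greedily (singleton initialisation, node
moves, aggregation) and then applies a Kernighan–Lin-style fine-tuning pass:
each pass moves every node exactly once — always taking the globally best
single move, even when it is locally unprofitable — and keeps the best
configuration visited. This escapes the single-move local optima that pure
greedy Louvain reaches on small dense graphs; on networks of up to 10 nodes
the returned $Q$ matches an exhaustive scan over all partitions (Bell(10) =
115,975) to numerical precision, which the acceptance suite verifies.

`consensusPartition()` repeats the stochastic optimisation (default 100
iterations), forms the co-assignment *agreement* matrix, thresholds it at
`tau` (default 0.5; the threshold is exposed because no canonical value
exists) and re-clusters the thresholded agreement matrix until all runs
agree. The reported `stability` is the fraction of subjects identically
assigned across all base iterations after optimal label alignment (an
assignment-problem match on the contingency table). The consensus $Q$ is
always evaluated on the *original* network.

Group profiles are characterised with Mann–Whitney U tests per scale and
group pair (exact when both groups have at most 8 observations and no ties,
otherwise the normal approximation with continuity and tie correction),
Bonferroni-corrected over all scale-by-pair tests in the call; chi-square
tests for categorical frequencies; and Welch t-tests for continuous
characteristics.

# Connectome construction and quality control

Motion exclusion is two-staged: subjects with mean framewise displacement
(FD) above 0.5 mm are removed first, then subjects with more than 20% motion
spikes (FD > 0.5 mm per volume). Both cutoffs are arguments. Mean-FC outliers
(average off-diagonal correlation more than 3 SD from the sample mean,
computed on the raw correlation matrices in a single pass) are removed next;
with the whole-sample SD convention a lone outlier can only exceed 3 SD when
the sample is larger than ~10 subjects, which is why the QC tests use 30+
subjects.

Proportional (cost) thresholding retains the strongest
$\lfloor \mathrm{cost} \cdot E \rfloor$ edges, $E = n(n-1)/2$. "Top 25% of
positive edges at the group level" is interpreted as *density* 0.25 of all
possible edges, selected from the positive edges of the group-mean matrix
(an error is raised if there are too few positive edges). The identical mask
is applied to every subject so that the same edges are compared across
individuals; an individual negative weight surviving the group mask is set to
0.001 rather than dropped, preserving the mask while minimising its
influence. Ties at the cut are broken by first occurrence in row-major
upper-triangle order so results are deterministic. Individual thresholding
(each subject's own top edges) and max-normalisation (weights divided by the
subject's largest weight) are provided for the robustness variant of the
analysis.

ICN features are the mean retained-edge weight within each of the 8 ICNs and
between each of the 28 ICN pairs — 36 features per subject; an empty block
yields 0 and is logged on the result.

# Graph metrics and null normalisation

All metrics operate on the thresholded positive-weight connectome with the
BCT weight-to-length convention $\ell_{ij} = 1/w_{ij}$:

* **strength**: $s_i = \sum_j w_{ij}$;
* **betweenness**: raw shortest-path counts on the length graph (percentile
  hub rules are rank-based, so no normalisation is needed);
* **clustering**: Onnela geometric-mean form
  $C_i = \frac{1}{k_i(k_i-1)} \sum_{jh} (\hat w_{ij} \hat w_{ih} \hat
  w_{jh})^{1/3}$ with $\hat w = w / \max w$;
* **characteristic path length**: mean shortest path over *reachable* pairs;
  disconnected pairs are excluded there and contribute 0 to global
  efficiency (mean inverse shortest path);
* **local efficiency**: global efficiency of each node's
  neighbour-induced subgraph, averaged;
* **participation coefficient**: $P_i = 1 - \sum_s (k_{is}/k_i)^2$ over the
  8 predefined ICN labels (subject-invariant; per-subject Louvain modules
  can be supplied instead via `modulePartition`);
* **within-module degree z**: within-module strength z-scored inside each
  module (z = 0 where a module's spread is zero);
* **modularity**: Louvain (+ fine-tuning) on the positive weights;
* **assortativity**: Pearson correlation of endpoint strengths over edges
  (both orientations); it is `NaN` with a warning when strengths are
  constant.

Null ensembles (`nullEnsemble()`, default 100 networks) use Maslov–Sneppen
double-edge swaps that carry the weights with the rewired edge slots, so the
degree sequence and the weight multiset are preserved exactly (the stricter
strength-preserving null is not implemented; degree + weight-multiset
matches the stated null class). The swap loop runs in compiled code with R's
RNG, so ensembles are seed-reproducible. Clustering, path length, global and
local efficiency, small-worldness and assortativity are divided by the null
means; strength and modularity are reported raw, and raw assortativity is
kept alongside because null assortativity is near zero and the ratio is
unstable. Small-worldness is reported both as the raw clustering/path-length
ratio and, after normalisation, in the $\sigma$ form (normalised clustering
divided by normalised path length), which is the definition used in the
normalised summary tables.

Robustness across costs uses the trapezoid AUC of a metric over the cost
grid (default 0.05–0.30).

# Hubs

One hub set is defined for the sample: per-subject nodal metrics are averaged
across included subjects, and percentiles are taken over regions with linear
interpolation. Connector hubs have betweenness *and* participation strictly
above the 70th percentile; provincial hubs have within-module degree z above
and participation strictly below it. Ties at the cut are excluded from
"above" sets, making the rules deterministic, conservative, and the two hub
types disjoint. Under independent metrics the expected connector fraction is
$0.3^2 = 9\%$ of regions, which the tests verify by simulation.

# PLS prediction of profile membership

Group membership is one-hot encoded (one column per group). Features are
residualised on covariates (age, sex, motion, mean FC) by training-set OLS
and standardised to mean 0 / SD 1; *all preprocessing parameters are
estimated on training subjects only* and re-applied to held-out subjects, a
property the tests check directly. Residualisation (rather than appending
covariates to the predictors) keeps the response block a clean one-hot
target; the alternative can be assembled manually by binding covariates to
the feature matrix.

`fitPLS()` is a NIPALS PLS2: components maximise predictor-response
covariance with deflation; at $k = \mathrm{rank}(X)$ the fitted values equal
multivariate least squares (an oracle test), and scores are mutually
orthogonal. Model selection uses stratified 5-fold cross-validation repeated
10 times (stratification prevents empty-group training folds at small n;
plain random splits are equivalent at large n). Prediction error is the
casewise RMSE — per held-out subject, the RMSE across the one-hot response
columns — averaged over subjects; classification accuracy (argmax of the
predicted scores, ties to the lowest group index) is always reported
alongside. The selected dimensionality $k^*$ is the smallest $k$ whose mean
RMSE is within one standard error (SD over the fold estimates divided by
$\sqrt{\text{folds} \times \text{repeats}}$) of the minimum.

Significance uses label permutations: the full cross-validation pipeline,
including fold-wise preprocessing, is re-run on shuffled group labels, and
$p = (1 + \#\{\mathrm{null} \le \mathrm{observed}\}) / (1 + n_{perm})$ — the
+1 correction keeps p-values valid and strictly positive. $k^*$ is held
fixed at the observed selection during permutation (a selection-inclusive
null is possible but much more expensive; with $k^*$ fixed the test is
calibrated, which the acceptance suite demonstrates empirically). The
AUC-over-costs variant applies the same machinery to the trapezoid AUC of
RMSE across thresholds.

Loading stability is assessed by bootstrap: the model is refit on resamples
of the subjects (preprocessing refit per resample), each resample's loading
matrix is aligned to the full-sample reference by the orthogonal Procrustes
rotation $R = UV^\top$ from the SVD of $L_b^\top L_{ref}$ (reflections
allowed — this also repairs component sign and order indeterminacy), and
each loading is summarised by its bootstrap mean, standard error, and their
ratio. Group differences in component scores are tested two-sidedly against
label permutations of the mean-difference statistic.

# ANCOVA of global metrics

Each global metric is modelled as `metric ~ group + covariates` with Type II
sums of squares for the group factor (no interactions are modelled, so Type
II is the natural choice; the output tables report $F$, $p$, and
partial eta squared $\eta_p^2 = SS_{group} / (SS_{group} + SS_{error})$).
Constant covariates are dropped (they are collinear with the intercept),
making the model reduce exactly to one-way ANOVA in that case; any other
rank deficiency is an error naming the collinear columns. Pairwise
follow-ups are Bonferroni-corrected. The across-cost variant reduces each
subject's metric curve to its AUC and tests the group F against label
permutations.

# The synthetic cohort generator

`cohortSpec()` defines the generator; defaults live in
`inst/extdata/default_cohort.yaml` and are synthetic choices, not estimates
from any empirical cohort:

* **Profiles.** Four groups: a comparison group at the T-score population
  mean (50) and three clinical-style profiles — C1 elevated on aggression,
  hyperactivity/impulsivity and peer problems; C2 on inattention and
  executive function; C3 on learning problems. Values were chosen so the
  centred profile *shapes* are mutually distinguishable, because the
  behavioural network correlates shapes: profiles that differ only in level
  are invisible to it. Per-scale noise is independent Gaussian (default SD
  5 T-score units), the simplest model in which recovery difficulty is
  governed by a single parameter; scores are rounded to integers and clipped
  to 10–90.
* **Time series.** Zero-mean multivariate Gaussian with an ICN block
  correlation structure (within-ICN r = 0.30, between-ICN r = 0.05, unit
  variance) plus additive group deltas; the shipped configuration plants
  +0.15 on limbic–dorsal-attention connectivity in C2 and −0.04 on
  fronto-parietal–default-mode connectivity in C1. No quantitative effect
  sizes exist to copy, so the deltas were fixed once at values a
  medium-sized cohort can detect. Default dimensions are 100 regions × 266
  volumes (a 464-region atlas can be emulated by setting `nRegions`).
* **Covariates.** Age uniform on 5–15 years; sex binary with P(male) = 0.65;
  FD traces log-normal (median ≈ 0.15 mm/volume) with a 3% chance per
  volume of a spike drawn from 0.55–1.5 mm, so both outcomes of the motion
  exclusion rules occur in tests.

What the generator does *not* emulate: haemodynamics, autocorrelated BOLD
noise, motion artefacts in the signal itself, scanner drift, heavy-tailed
behavioural distributions, and missing data. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under the
assumed model, not that real paediatric cohorts will show comparable effect
sizes or recovery rates.

# Numerical choices and problem sizes

* All randomised functions take an explicit seed and restore the caller's
  RNG state; stage seeds in the pipeline derive deterministically from one
  master seed, and two runs with the same configuration produce
  byte-identical artefact bundles.
* Louvain move gains use a 1e-10 improvement tolerance; Q invariants are
  validated at 1e-10, and small-graph optimality at 1e-9.
* NIPALS converges at a relative score change of 1e-10 (cap 500
  iterations); a vanishing component norm signals that `k` exceeds the
  predictor rank and raises an error.
* Bonferroni corrections are `min(1, p * number of tests in the call)`.
* The test and demonstration problem sizes were set to what a laptop-class
  single core handles comfortably: recovery checks at 300 subjects,
  calibration at 200 null cohorts of 80 subjects with 99 permutations,
  power at 20 cohorts of 200 subjects, null ensembles of 100 networks at
  100 regions, and the demonstration pipeline in `scripts/acceptance.R`
  at 120 subjects with scaled-down inference (199 permutations, 200
  bootstrap resamples, 8-network null ensembles). Full-scale inference
  (1000 permutations and resamples, 100-network ensembles) is a
  configuration change, not a code change.

# Known limitations

* The signed-modularity convention and the agreement threshold `tau` are
  exposed as configuration because no single canonical choice exists for
  correlation networks.
* Community detection on correlation networks ignores absolute severity
  (a limitation of shape-based similarity); distance-based alternatives are
  out of scope.
* The permutation null keeps the selected component count fixed; it does not
  account for selection variability.
* Null ensembles preserve degrees and the weight multiset but not per-node
  strengths.
* `fcOutlierFilter()` is single-pass; with very small samples no subject can
  exceed the 3 SD whole-sample bound.
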