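---
title: "Metabolic covariance network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The problem

Regional glucose uptake measured by FDG-PET covaries across subjects:
regions that work together metabolically rise and fall together across a
cohort. Treating each atlas region (ROI) as a node and the between-subject
covariation of ROI uptake as edges yields a *metabolic covariance network*
per diagnostic group. Graph-theoretic summaries of these networks — and the
left–right balance of hemispheric network efficiency — can separate dementia
syndromes whose raw uptake maps look similar. metabnet implements that whole
pipeline for subject × ROI tables over a 90-region AAL-style parcellation
(cerebellum excluded), together with a synthetic cohort generator so every
stage is testable without patient scans.

## Network construction

For each group, the association between ROIs $i$ and $j$ is the partial
correlation controlling age and sex: each ROI's signal is residualized on
(intercept, age, sex) and the residuals are Pearson-correlated
(`partial_correlation()`). This equals the textbook partial correlation for
linear covariates, which we verify in the tests against an inverse-covariance
oracle. Covariate columns that are constant within a group (e.g. one sex) are
absorbed by the intercept and dropped.

The symmetric matrix is binarized by a *sparsity threshold*: at sparsity $s$,
exactly $\mathrm{round}(s \cdot P)$ of the $P = R(R-1)/2$ node pairs with the
strongest connections become edges (`binarize_at_sparsity()`). Pairs are
ranked by signed correlation (an `absolute` mode exists behind a flag):
at the sparsities analyzed here (6–40%) strong positive covariance dominates
the retained edges. Ties at the threshold boundary are broken in
lexicographic pair order, which makes the edge count exact and the result
deterministic; edge counts use R's round-half-to-even. At the hub-analysis
sparsity of 28% a 90-node network keeps $\mathrm{round}(0.28 \times 4005) =
1121$ edges. `sparsity_sweep()` applies the rule over 6–40% in 1% steps (35
levels); because all levels rank the same pairs, edge sets are nested across
the sweep.

## Graph metrics and the null model

On each binary network we compute (`graph_metrics` functions):

* clustering coefficient $C$ (per node: triangles over $k(k-1)/2$, 0 for
  degree < 2; averaged),
* characteristic path length $L$ (mean shortest path over connected pairs;
  disconnected pairs are excluded and counted),
* global efficiency $E_{glob}$ (mean inverse shortest path, 0 for
  disconnected pairs) and local efficiency $E_{loc}$ (mean over nodes of the
  global efficiency of the neighbour-induced subgraph, node excluded, 0 for
  degree < 2),
* betweenness centrality $BC$, normalized per node as $b_i = BC/\overline{BC}$,
  with nodes above $b_i > 1.5$ flagged as candidate hubs.

Note that several toolboxes compute local efficiency with paths allowed to
leave the neighbourhood (the Latapy variant); metabnet uses the
induced-subgraph definition and cross-checks it against brute-force
enumeration in the tests.

Small-world indices are normalized against degree-preserving surrogates:
$\gamma = C/C_{null}$, $\lambda = L/L_{null}$, $\sigma = \gamma/\lambda$,
where the null values are means over rewired graphs produced by
double-edge swaps (`rewire_degree_preserving()`), counting *accepted* swaps —
by default 100 surrogates with 10 accepted swaps per edge. The number of
surrogates and swap density are configurable; 10 surrogates with 5 swaps per
edge already stabilize $\sigma$ to within a few percent on 90-node networks
and are what the bundled acceptance script uses for its sweep summaries. A
degree sequence that admits no swap (e.g. a complete graph) returns
$\gamma = \lambda = \sigma = 1$ with a warning.

Hub detection runs at a single sparsity, default 28%, chosen as the smallest
level at which the group networks are typically fully connected; a
connectivity check warns otherwise.

## Group comparison

`permutation_test()` compares any metric between two groups at every
sparsity: the observed statistic is the group-A-minus-group-B metric
difference; the null is built by relabelling subjects into pseudo-groups of
the original sizes and rebuilding both networks per permutation (covariates
travel with subjects). The two-tailed p-value uses the add-one convention
$p = (1 + \#\{|d^\ast| \ge |d|\})/(1 + n_{perm})$, so $p \in
[1/(n_{perm}+1), 1]$. The study convention is 1000 permutations. Per-sparsity
p-values are reported without multiplicity correction across the 35 levels —
mirroring how significant sparsity ranges are conventionally quoted — and
`significant_ranges()` collapses them into maximal contiguous percent
intervals. We chose the raw (unstudentized) metric difference as the test
statistic; the permutation null makes it exact either way.

## Seed-based correlation analysis

`seed_map()` correlates a seed ROI (default MTG.R, the right middle temporal
gyrus) with all other ROIs across the subjects of a group, using plain
Pearson correlation (covariate residualization is available behind a flag
but off by default, matching the convention for seed maps). Correlations are
variance-stabilized by Fisher's transform $z = \tfrac12\ln((1+r)/(1-r))$
(natural log), and two groups are compared per target by

$$Z = \frac{z_1 - z_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}},$$

with two-tailed normal p-values and Benjamini–Hochberg FDR control at 0.05.
Some sources typeset this statistic without the square root over the
variance sum; the square-root denominator is the standard two-sample
comparison of Fisher-z-transformed correlations and is what metabnet
implements. ROI-level maps (89 targets) stand in for voxelwise maps; the
statistics are identical per element.

## Hemispheric asymmetry

`split_hemispheres()` partitions the table into 45 left and 45 right
regions; each hemisphere's network is built independently and binarized at
the same sparsity (default 28%), and global/local efficiencies $M_L$, $M_R$
are compared. The asymmetry index is

$$AI = 200 \cdot \frac{|M_R - M_L|}{M_R + M_L},$$

a percent-like, non-negative, scale-invariant imbalance measure (note that
applying this formula to left/right global efficiencies of 0.6247 and 0.6253
gives $AI \approx 0.096$ — published AI values for control groups near 0.9
are not reproducible from their own printed efficiencies, so the formula is
implemented as written and this discrepancy is simply documented).

Within-group inference (`within_group_test()`) reads "random sampling
permutation test" as resampling subjects. Two schemes are provided:

* **Subject-level hemisphere sign-flips (default for the p-value).** Each
  subject's left and right blocks are swapped independently with probability
  1/2 (homotopic regions aligned by the atlas), and both pseudo-hemisphere
  networks rebuilt. Under the null of mirror symmetry the per-subject
  (left, right) pair is exchangeable, so this is a calibrated permutation
  test of $M_R = M_L$. Null simulations in the test suite confirm type-I
  error consistent with the nominal 0.05.
* **Subject bootstrap (for AI distributions).** Resampling subjects with
  replacement gives sampling distributions of $M_L$, $M_R$ and AI used by
  the between-group Welch t-test on AI (`compare_ai_between_groups()`).
  The crossing-zero bootstrap p-value is also available
  (`method = "bootstrap"`), but bootstrapping correlation-matrix functionals
  at cohort-scale n (~20 subjects) inflates the spread of the resampled
  difference — duplicated subjects add correlation noise — and we measured
  its type-I error near zero. It is therefore not the default for the
  within-group test; this is a deliberate deviation motivated purely by
  calibration, and both schemes are exposed.

## The synthetic cohort generator

`generate_cohort()` draws subject × ROI tables from a planted ground truth
(`planted_structure()`), designed to emulate the study conditions: four
groups (HC/AD/PDD/DLB) of 22/22/18/22 subjects, 90 ROIs, age uniform on
55–75 years, sex Bernoulli(0.5), and mild linear age/sex effects on ROI
means that confound raw correlations (defaults −0.03 signal units/year and
0.2 for sex, small relative to the unit signal SD) — exactly what the
partial correlation is there to remove. Signals are multivariate normal:
the planted partial-correlation weights define a precision matrix whose
inverse (standardized) is the population correlation; independent
measurement noise (SD 0.5) attenuates observable correlations by a factor
0.8. Normality is an explicit modeling choice matching the
Pearson/partial-correlation machinery; no distributional model of real ROI
uptake is claimed.

The planted topology mirrors a parcellated brain: homotopic left/right
pairs coupled at weight 0.15, five communities per hemisphere with
within-community weight 0.05, and four bilateral hub pairs wired to 80% of
their hemisphere at weight 0.045. These effect sizes were chosen for test
power (hubs recoverable as $b_i > 1.5$ nodes from n = 200 cohorts in ≥ 90%
of replicates), not for biological fidelity; no published effect sizes exist
for group covariance differences.

`plant_asymmetry()` multiplies one hemisphere's internal weights by a gain.
A non-obvious but robust consequence of fixed-sparsity binarization: the
*gained* hemisphere becomes more segregated (its retained edges concentrate
inside saturated communities) and its global efficiency *falls*. Rightward
efficiency asymmetry ($M_R > M_L$) is therefore planted by gaining the
*left* hemisphere. We verified this direction on the noiseless population
correlation matrix; it is asserted in the tests. The asymmetry power
fixture uses a lighter base structure (weights 0.03/0.10/0.025) so that a
gain of 2 keeps the precision matrix positive definite; at that effect size
and n = 200 subjects the rightward direction is recovered in ≈ 90% of
replicates at the default sparsity. Group defaults plant mild gains (1.05
left for AD, 1.05 right for PDD, 1.08 left for DLB) — realistic direction
assignments, not calibrated for detectability at n ≈ 20.

What the generator does **not** emulate: voxel-level point spread and
partial-volume effects, non-Gaussian uptake distributions, longitudinal
decline, scanner batch effects, or group differences in mean uptake level.
Passing tests therefore demonstrate the correctness and calibration of the
pipeline's machinery on data satisfying its assumptions — not that real
cohorts of this size would show these effects.

## Numerical choices and degenerate inputs

* Binarization requires a fully defined association matrix; NA entries
  (zero-variance residuals) abort with the offending ROIs named earlier.
* Ties in binarization: lexicographic pair order (documented above).
* $L$ excludes disconnected pairs (reported alongside); efficiencies count
  them as 0 — this keeps both finite on fragmenting networks.
* $b_i$ normalizes by the mean BC over *all* nodes including zeros; a zero
  mean (complete graph) yields undefined $b_i$, no hubs, and a warning.
* Permutation and resampling p-values use add-one smoothing and never reach 0.
* The master seed of `run_pipeline()` derives per-stage seeds
  deterministically; reruns are byte-identical.
* Resamples that produce a zero-variance ROI are redrawn and counted
  (`n_redrawn`).

## Problem sizes used by the bundled checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
desk scale: oracle comparisons on 200 random graphs of ≤ 12 nodes;
calibration on 100 (tests) or 40 (script) simulated null cohorts with 200
permutations/replicates each; recovery on 50 (tests) or 30 (script)
replicates of n = 200 cohorts; sweep summaries with 10 surrogates and 5
swaps per edge. These sizes keep the full run in minutes while leaving
Monte-Carlo error well inside the asserted margins.

## Known limitations

* Group-level networks only: no per-subject networks, no weighted variants,
  no modularity/rich-club analysis, and no sparse inverse covariance
  (graphical lasso) estimation.
* The partial correlation controls the listed covariates pairwise; it is not
  the full-precision-matrix partial correlation among all ROIs.
* No multiplicity correction across sparsity levels (by design, see above).
* Voxel-level seed maps are replaced by ROI-level maps; a NIfTI ROI-mean
  extractor (`extract_roi_means()`) is provided, but spatial normalization
  and smoothing are upstream of this package.
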