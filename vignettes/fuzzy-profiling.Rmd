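---
title: "Fuzzy cognitive-behavioral profiling: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy cognitive-behavioral profiling: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyprofiles)
```

## The problem

Pediatric psychiatry increasingly treats cognition and behavior as
continua rather than discrete diagnostic categories. Given six
standardized per-subject scores — three latent cognitive factors (verbal
ability `VA`, executive function/processing speed `EFPS`, memory `MEM`)
and three behavioral scales (`internalizing`, `externalizing`, `stress`)
— this package extracts *fuzzy profiles*: prototype patterns in the
6-dimensional feature space together with, for every subject, a vector of
membership values in `[0, 1]` summing to 1. A subject is never forced
into one box; two children near a profile boundary keep their similarity
instead of being split across a hard cluster edge. The fitted centroids
are portable: a new cohort — even a single child — can be mapped onto an
existing referential without refitting.

## Models and procedures

### Preprocessing

Features are harmonized (z-scored within cohort-by-timepoint), any
feature declared missing for a whole cohort is imputed by an unweighted
K-nearest-neighbor mean over the standardized remaining features
(default `k = 5` donors), and each feature is then replaced by its
standardized least-squares residual on the covariates (age in months,
sex, ethnicity, handedness; categorical covariates treatment-coded
against the most frequent level). Location/scale z-scoring is the
harmonization backend: it is the minimal transform consistent with
per-cohort means of 0 and standard deviations of 1 after harmonization,
it is idempotent, and it needs no empirical-Bayes machinery at these
cohort sizes. The stage order — harmonize, impute, residualize,
re-standardize — means imputation distances are computed on comparable
scales and residuals are exactly orthogonal to every covariate column.

### Latent cognitive factors

When only raw subtest scores are available, the three cognitive factors
are estimated by split-half exploratory factor analysis: a balanced
(optionally stratified) random split; iterated principal-axis factoring
on the first half (communalities initialized at squared multiple
correlations, iterated to `max |Delta h| < 1e-6`, Heywood cases clipped);
rotation; regression-method (Thurstone) scores `s = z R^-1 (lambda Phi)`.
The held-out half is refit and compared by Tucker congruence
(replication threshold 0.9) — a deliberate, lightweight stand-in for a
full confirmatory model: it checks exactly the property downstream
stages need (a stable loading pattern) without fit-index machinery.
Principal-axis factoring was chosen over maximum likelihood because it
makes no normality assumption and is robust on bounded questionnaire
scores. The default rotation is promax: cognitive factors correlate, so
an oblique rotation is appropriate, and promax is the standard oblique
method available in base R; varimax and no rotation are the
alternatives.

### Fuzzy C-means and Mahalanobis memberships

Profiles are fitted by fuzzy C-means (FCM): alternating minimization of

$$J(U, C) = \sum_{i=1}^{k}\sum_{s=1}^{n} u_{is}^m \,\lVert x_s - c_i\rVert^2,
\qquad
u_{is} = \Big(\sum_{j} (d_{is}/d_{js})^{2/(m-1)}\Big)^{-1},
\qquad
c_i = \frac{\sum_s u_{is}^m x_s}{\sum_s u_{is}^m},$$

run until the largest membership change falls below `tol = 1e-6` (cap
1000 iterations), best of `n_init = 10` seeded restarts. The objective is
asserted non-increasing at every iteration. The fuzzifier defaults to
`m = 2`, the conventional choice; `m -> 1` recovers hard k-means.

Fitting is Euclidean; *memberships* — for the fitting cohort and for any
predicted cohort — are then computed from Mahalanobis distances
$d_{is} = \sqrt{(x_s-c_i)^\top \Sigma_i^{-1} (x_s-c_i)}$ using
per-profile membership-weighted covariances
$\Sigma_i = \sum_s u_{is}^m (x_s-c_i)(x_s-c_i)^\top / \sum_s u_{is}^m$,
regularized by `1e-6 * trace/6` on the diagonal so they are always
positive definite. Separating the fit metric from the membership metric
keeps the fit simple and convex-step-wise while letting memberships
respect each profile's shape. A subject exactly at a centroid gets that
profile's indicator row; exact zero-distance ties split equally.
Prediction for new subjects applies the identical formula with stored
centroids and covariances — no refit, valid for a single row.

The number of profiles is chosen by the mean silhouette of the hardened
(argmax) partition over a candidate range (default 2–10). Hardened
silhouette is used because the silhouette statistic is defined for crisp
partitions and makes selection comparable with the broader clustering
literature; a candidate that leaves a hardened profile empty is scored
`-Inf`.

Centroid labels are rule-based and deterministic: the cognitive tier
(`H`/`M`/`L`) compares the mean of the three cognitive coordinates with
`±0.5` sd, and the behavioral tag lists which behavioral coordinates
exceed `+0.5` sd (`S`tress, `I`nternalizing, `E`xternalizing), or `LB`
when none does — yielding the familiar `HC/LB`, `LC/LB`, `MC/HSI`,
`MC/HE` pattern.

### The membership graph and the aggregation test

Memberships define a bipartite graph: subjects and centroids are nodes,
each subject-centroid edge carries weight `u` and traversal distance
`1 - u` (default; `-log u` available). All subject-subject proximity
flows through centroids, so two subjects sharing a strong profile are two
short hops apart. For a labeled subject set (a diagnosis, or the
any-diagnosis PSYPATHO index) the average shortest weighted path (ASWP)
over all pairs measures aggregation; its null distribution comes from
5000 equally sized uniform subject subsets, and p-values use add-one
smoothing `(count + 1)/(B + 1)`. Under the `1 - u` distance a *smaller*
ASWP means tighter aggregation, so the left tail is the compactness
test; both tails are always reported, and the transform is configurable,
because the direction convention differs across descriptions of
shortest-path statistics on similarity weights. Benjamini-Hochberg
correction is applied across the diagnosis family within each cohort.

On a bipartite `1 - u` graph the subject-subject shortest distance has a
closed form, $\min_i (1-u_{ia}) + (1-u_{ib})$: any longer path through
two centroids costs at least $2 - u_{ic} - u_{jc} \ge 1$ on its middle
hops. The implementation uses the graph engine; the closed form is kept
as an independent oracle in the tests.

### Longitudinal transitions

Each follow-up is profiled by an *independent* FCM fit (not predicted),
and profiles are aligned to the first-timepoint model by optimal
assignment on centroid Euclidean distance before transitions are
computed. Over subjects present at both timepoints, the package reports
the from/to count matrix, the stability percentage
(`100 * trace / n`), and per-origin movement ratios — the fraction of a
profile's members whose primary (argmax) profile changes — displayed as
`"0.55 (54.91%)"`. Three-timepoint trajectories are exported as a path
count table (the Sankey table). Exact membership ties harden to the
lowest profile index and are flagged.

### Environmental associations

Associations between environmental predictors and memberships use
NIPALS PLS2 with all membership columns as joint responses — memberships
are compositional and strongly collinear, which PLSR tolerates by
construction and ordinary least squares does not. Predictors are
standardized (ordinal predictors as numeric; missing values mean-imputed
with a logged count); responses are centered, which makes each
predictor's coefficients sum to zero across profiles. The number of
components is chosen by 10-fold cross-validated `Q^2` with a parsimony
rule: a larger component count is accepted only when it improves `Q^2`
by more than 0.01. Plain argmax over `Q^2` was measured to chase
noise-level PRESS gains and select the largest candidate; the
improvement threshold recovers the planted dimensionality in
simulations while never giving up more than 1% of predictive `R^2`.
Significance uses 10,000 joint row permutations of the response block:
the model p-value is the right tail of the null `R^2`, coefficient
p-values the two-sided tails of the null absolute coefficients (one
shared permutation stream), and BH-FDR is applied over the full
predictor-by-profile coefficient family within a model, with threshold
`p_fdr < 0.05`.

## The synthetic study generator

Real pediatric cohorts of this kind are access-restricted, so the
package ships a seeded generator used by every test and by the
acceptance script. It plants: four profile centroids in the standardized
6-feature space (two large low-behavior profiles split by cognition at
`±0.9` sd; two smaller moderate-cognition profiles with elevated
internalizing/stress or externalizing at `+1.1`–`+1.3` sd), with mixing
weights 0.168/0.146/0.356/0.330 echoing the relative profile sizes
reported for a large general pediatric population; Gaussian
within-profile scatter with correlated blocks (0.4 among cognitive, 0.3
among behavioral features); per-cohort location/scale batch shifts;
small covariate effects (age slope, a sex effect on the behavioral
scales, handedness); diagnoses drawn from Bernoulli models whose
log-odds are linear in the true membership vector, enriching
externalizing disorders (ADHD, CD, ODD) in the high-externalizing
profile and anxiety/OCD in the high-internalizing profile at realistic
prevalences; an environmental block linearly driven by true memberships
plus unit noise; a 65%-stay transition matrix between timepoints; and
one behavioral scale (`stress`) blanked in one validation cohort — the
missing-variable pattern the imputation stage exists for.

The default within-profile standard deviation is 0.4, making the closest
pair of planted centroids about 4.4 within-profile sd apart (roughly 5%
hard-assignment confusion). This is the calibration at which the planted
structure is identifiable yet memberships remain visibly graded — the
regime the method targets. Larger overlap makes the two
behavior-differentiated profiles merge under any centroid-based method;
test outcomes at that calibration would measure the geometry, not the
implementation.

What the generator does *not* emulate: item-level questionnaire
structure, floor/ceiling effects, non-Gaussian heavy tails, informative
missingness, site effects within a cohort, and measurement invariance
violations across cohorts. Passing tests therefore demonstrate
correctness of the algorithms under the planted model, not robustness to
every pathology of real survey data.

## Numerical choices and degenerate inputs

- FCM: `tol = 1e-6` on the membership matrix, 1000-iteration cap, 10
  restarts; centroid initialization samples distinct subjects with tiny
  jitter. `k >= n`, all-identical points, and non-finite features are
  errors; zero distances follow the indicator rule.
- Covariances: `eps = 1e-6 * trace/p` ridge; vanishing total membership
  weight for a profile is an error rather than a silent singular matrix.
- Factor analysis: non-convergence after 1000 communality iterations is
  an error reporting the last change; Heywood communalities clip to
  `1 - 1e-6` with a warning; a numerically singular subtest correlation
  gets an `eps = 1e-8 * trace/p` ridge with a warning.
- Harmonization: a constant feature within a cohort is an error naming
  cohort and feature; an all-missing cohort-feature cell (the declared
  missing pattern) passes through for imputation.
- Rank-deficient covariate designs drop aliased columns with a warning;
  residuals stay orthogonal to the full covariate span.
- Ties: membership ties harden to the lowest profile index and are
  flagged; duplicate centroid labels get index suffixes.
- p-values use add-one smoothing, so 0 is never reported.
- All stochastic stages draw deterministic substreams from one global
  seed ([substream_seed()]), so a whole study reruns byte-identically.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data
at desk scale: n = 2000 for the reference cohort (200–270 for validation
cohorts), 800 subjects for model-count selection studies, 500 subjects
for permutation calibration (B = 199 nulls over 200 replicates), and the
pipeline's full permutation budgets (B = 5000 graph, B = 10,000
regression) on the reference cohort. These sizes were chosen to estimate
every reported quantity within Monte-Carlo error of a few percent.

## Known limitations

- Silhouette on hardened labels is conservative at strong overlap: on
  the default generator it can prefer merging the two
  behavior-differentiated profiles (k = 3) even though the planted k = 4
  is recoverable when k is given — the same ambiguity any crisp
  model-count criterion has on genuinely fuzzy data. The full silhouette
  table is always returned so the margin is visible.
- FCM centroids at `m = 2` are mildly shrunk toward the grand mean by
  soft weighting; recovery error is therefore reported per coordinate
  (RMSE in sd units), and per-profile Euclidean error carries an
  irreducible bias term of similar magnitude.
- The aggregation test conditions on the fitted graph; it does not
  propagate uncertainty in the memberships themselves.
- KNN imputation is single imputation; downstream variances are
  conditionally biased for the imputed cohort-feature.
- Harmonization removes location/scale batch effects only.
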