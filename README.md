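# fuzzyprofiles

Fuzzy cognitive-behavioral profiling for pediatric cohort studies.

Children do not fall into crisp diagnostic boxes: cognition and behavior
form overlapping continua. `fuzzyprofiles` models them that way. From six
standardized per-subject scores — three latent cognitive factors (verbal
ability **VA**, executive function/processing speed **EFPS**, memory
**MEM**) and three behavioral scales (**internalizing**,
**externalizing**, **stress**) — it extracts *fuzzy profiles* by fuzzy
C-means clustering and assigns every subject a membership vector
$u_s \in [0,1]^k$, $\sum_i u_{is} = 1$, computed from Mahalanobis
distances to the profile centroids:

$$u_{is} = \Big(\sum_{j=1}^{k} (d_{is}/d_{js})^{2/(m-1)}\Big)^{-1},
\qquad d_{is} = \sqrt{(x_s-c_i)^\top \Sigma_i^{-1} (x_s-c_i)} .$$

Because the formula needs only stored centroids and covariances, a fitted
referential transfers to new cohorts — down to a single child — without
refitting. Around that core the package provides:

- **Preprocessing**: cross-cohort harmonization, covariate
  residualization (age, sex, ethnicity, handedness), KNN imputation of a
  cohort-missing scale.
- **Latent factors**: split-half exploratory factor analysis
  (principal-axis + promax) with Thurstone regression scores and a
  congruence-based replication check.
- **Model selection**: silhouette over candidate profile counts;
  deterministic centroid labeling (`HC/LB`, `LC/LB`, `MC/HSI`, `MC/HE`).
- **Diagnosis aggregation**: a bipartite subject-centroid graph with
  `1 - u` edge distances, the average shortest weighted path (ASWP) of a
  diagnosis group, and a 5000-draw permutation test with BH-FDR across
  diagnoses (plus the any-diagnosis PSYPATHO index).
- **Longitudinal stability**: independent per-timepoint fits aligned by
  optimal centroid matching; stability percentages, movement ratios
  (`"0.55 (54.91%)"` display), Sankey path tables.
- **Environmental associations**: NIPALS PLS2 of predictors on
  memberships, 10-fold cross-validated component selection, 10,000-draw
  permutation inference, BH-FDR over the coefficient family.
- **A seeded synthetic study generator** with planted profiles, cohort
  shifts, diagnosis enrichment, environmental effects, timepoint
  transitions and a missing-variable pattern — the ground-truth substrate
  for every test.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for each result type.

## Worked example

```r
library(fuzzyprofiles)

# A synthetic three-cohort study with 4 planted profiles,
# 3 timepoints for the reference cohort, and the stress scale
# missing in the GESTE cohort.
synth <- generate_cohorts(synthetic_spec(), seed = 1)
cfg   <- run_config(seed = 42)
study <- run_study(synth$data, cfg, k = 4)
study
```

```
Fuzzy profile study (k = 4 )
Profiles: HC/LB, MC/HSIE, LC/LB, MC/HE
Cohorts: ABCD, BANDA, GESTE

Diagnosis aggregation (ASWP):
     label      aswp     p_left  p_left_fdr
1       AD 1.0223849 0.00019996 0.000279944
2     ADHD 1.0133872 0.00019996 0.000279944
3       CD 0.9809704 0.00019996 0.000279944
4       DD 1.0684313 0.11777644 0.117776445
5      OCD 1.0631060 0.04139172 0.048290342
6      ODD 0.9889840 0.00019996 0.000279944
7 PSYPATHO 1.0487129 0.00019996 0.000279944

T1_to_T2: 61.05% stable

T2_to_T3: 63.60% stable

Environment PLSR: R^2 = 0.178 , model p = 1e-04
```

Reading the output:

- the four profiles reproduce the expected geometry — two large
  low-behavior profiles split by cognition (`HC/LB`, `LC/LB`) and two
  smaller moderate-cognition/high-behavior profiles (here labeled
  `MC/HSIE` and `MC/HE`: at this overlap the fitted stress/internalizing
  centroid also edges past the +0.5 sd externalizing threshold);
- most diagnoses aggregate non-randomly on the membership graph
  (left-tail ASWP p-values small after FDR), because the generator
  plants diagnosis log-odds that rise with specific profile memberships;
  the rare depression flag is the exception at this sample size;
- about two-thirds of subjects keep their primary profile between
  timepoints, matching the planted 65%-stay transition matrix;
- the environmental block, generated with a known linear effect on
  memberships, yields a significant PLSR with sign-consistent
  coefficients (`tidy(study$plsr)` for the full table).

Individual stages are ordinary functions you can pipe:

```r
pp  <- preprocess_features(synth$data, features = c("VA","EFPS","MEM",
         "internalizing","externalizing","stress"),
         covariates = c("age_months","sex","ethnicity","handedness"),
         impute_target = "stress")
fit <- fit_fcm(dplyr::filter(pp, cohort == "ABCD", timepoint == "T1"),
               colnames(synthetic_spec()$centroids), k = 4, seed = 7) |>
  label_profiles()
u_geste <- predict(fit, dplyr::filter(pp, cohort == "GESTE"))
```

## Documentation

The methods vignette (`vignettes/fuzzy-profiling.Rmd`) documents the
models, the tunable parameters and their defaults, the synthetic
generator's calibration and what it does and does not emulate, numerical
edge-case handling, and known limitations.
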