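---
title: "Stratifying autism severity from functional connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying autism severity from functional connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state functional connectivity (FC) differences between autism
spectrum disorder (ASD) and control groups are individually small, which
makes single edges useless as diagnostic markers. A more promising
question is whether multivariate FC patterns can *stratify* a
high-functioning ASD cohort (full IQ >= 70) by symptom severity, and
predict severity scores, in a way that survives honest accounting for
selection and overfitting. `fcstrat` implements such a pipeline end to
end:

1. **Connectome construction.** Per subject, ROI time series (e.g. a
   94-region AAL-2 parcellation, giving 94·93/2 = 4,371 edges) are
   correlated (Pearson), Fisher z-transformed, and standardized within
   subject; nuisance covariates (age, sex, full IQ, mean framewise
   displacement, site) are regressed out of every edge by OLS.
2. **Screening.** Edges are screened by Spearman correlation against the
   three ADOS subscales (Communication, Social Interaction,
   Restricted/Stereotyped Behaviors), keeping edges associated with at
   least one subscale (min-p across the three) at p < 0.005.
3. **CCA.** Canonical correlation analysis between the screened edges
   and the three subscales yields three components maximizing the
   explained subscale variance, summarized by the canonical correlations
   R_i, Wilks' Λ = Π(1 − R_i²), and η² = 1 − Λ.
4. **Whole-pipeline permutation.** Because screening + CCA on k ≈ 0.4·n
   features overfits massively, inference shuffles the subscale rows and
   re-runs the *entire* chain — top-k re-screening at the observed
   selection size, CCA refit, Ward re-clustering, cluster contrast — at
   every iteration. This yields selection-aware p-values and a
   null-adjusted effect size
   adj-η² = (η²_obs − mean η²_null)/(1 − mean η²_null).
5. **Clustering.** Significant canonical components are Ward-clustered
   (Euclidean distance, `ward.D2`); the 2-cluster cut defines
   severe/mild subgroups (higher mean ADOS total = severe), with a
   silhouette scan over k = 2..10 as a model-selection check.
6. **Agreement.** The FC-based partition is compared with ADOS-cutoff
   partitions (severe iff total >= cutoff) over a sweep of cutoffs:
   percentage of agreement, sensitivity, specificity, in both reference
   orientations.
7. **Biomarkers.** Each subgroup is contrasted with controls on all
   edges (pooled t-tests, BH-FDR at 0.05); significant edges are
   sign-aligned (edges with negative t multiplied by −1) and summed into
   a composite tested for *graded change*: severe > mild > control, two
   one-tailed tests.
8. **Prediction.** The top severity-discriminating screened edges (BH-FDR
   among the screened set, capped at 20) feed an RBF-kernel SVM
   (LIBSVM defaults: cost 1, γ = 1/m, no tuning) predicting ADOS totals
   under 10-fold cross-validation, then validated on an independent
   held-out ASD group; accuracy is the Pearson correlation between
   predicted and observed totals with one-tailed significance on
   n − 2 df.

## Data containers

`FCExperiment` extends `SummarizedExperiment`: rows are edges (with
`roi_a < roi_b` and a `"ROIa--ROIb"` label in `rowData`), columns are
subjects, `colData` is the phenotype table. A `stage` slot
(`raw_r → fisher_z → standardized → residualized`) only moves forward,
so a residualized object cannot silently re-enter the pipeline
upstream. `CCAResult`, `PartitionResult` and `PredictionResult` hold
the stage outputs with validity checks (ordered canonical correlations,
Λ and η² identities, label levels, matched prediction lengths).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `screening_p_threshold` | 0.005 | Spearman min-p cut for the observed screen |
| `screening_k` | 100 | selection size for permutation re-screens / `top_k` mode |
| `n_permutations` | 10,000 | whole-pipeline permutation iterations |
| `fdr_q` | 0.05 | BH-FDR level for biomarker and feature selection |
| `cutoff_range` | 9–17 | ADOS cutoffs swept in the agreement analysis |
| `n_folds` | 10 | CV folds (260 subjects → 234 train / 26 test) |
| `prediction_feature_cap` | 20 | edges entering the SVM |
| `iq_min`, `fd_threshold`, `age_range` | 70, 0.5 mm, [6, 30] y | inclusion bounds |
| `ados_min_exclusive` | 7 | ASD kept only with total > 7 (strict) |
| `min_asd_per_site` | 3 | site-size rule for stable site effects |
| `svm_mode` | classification | integer totals as classes; regression available |

Filters run in a fixed order: individual bounds, then the ADOS rule,
then the site-size rule (so a site is judged on the subjects that
individually qualify), then group assignment. ADOS totals are always
recomputed as Communication + Social Interaction; the RRB subscale
never enters the total. Discovery subjects need all three subscales;
validation subjects need a total plus at least one missing subscale and
(by default) sites disjoint from discovery/control sites.

## Interpretation choices the data leave open

* **Within-subject standardization.** "Standardized z-scores per
  subject's FCs" is read as centering/scaling each subject's 4,371-edge
  vector (population SD, divisor n). The alternative — per-edge across
  subjects within site — is available via
  `standardizeSubjects(mode = "per_edge_within_site")`.
* **Pooled t.** The two-sample tests use the Student (pooled-variance)
  form: it exactly reproduces the reference cohort table from its
  printed means/SDs/ns (t = −8.95, D = −0.67 for full IQ), which the
  Welch form does not. Covariate control residualizes both groups
  jointly and reduces df by the number of covariate columns. Cohen's D
  then obeys D = t·√(1/n₁ + 1/n₂).
* **adj-η².** The shrinkage form against the permutation-null mean is
  used. It is consistent with a published η²/adj-η² pair under
  top-100-of-4,371 selection and reduces to ~0 on null data (verified
  in the calibration tests).
* **Components entering clustering.** Components with permutation
  p < 0.05; if at least one is significant, only those are used (the
  2-cluster Ward cut is well defined in one dimension); if none, all
  components are used with a warning.
* **Ridge-free CCA.** `fitCCA` uses the SVD formulation (orthonormal
  bases, then SVD of their cross-product), which handles k ≈ n without
  regularization and matches a direct eigendecomposition oracle to
  1e−8 on full-rank instances. The Bartlett χ² p-value is retained as
  `naiveP` purely to demonstrate how anticonservative selection-unaware
  inference is (it rejects essentially always on null cohorts).
* **SVM mode.** Classification on integer totals is the faithful
  default (multi-class C-classification, RBF kernel, library defaults);
  epsilon-regression is provided as the statistically natural
  alternative. Defaults are recorded in the result's config snapshot.
* **Correlation significance** uses t = r√(n−2)/√(1−r²) throughout
  (r = 0.30, n = 260 gives t ≈ 5.05 under this formula).

## The synthetic cohort generator

There is no public fixture that exercises every stage with known
answers, so `simulateCohort()` plants the full causal structure:

* **Covariates and sites.** Age ~ N(15, 5²) clipped to [6, 30], IQ
  clipped at 70, male fraction 0.9 in ASD / 0.7 in controls (matching
  the reference cohort's 91.15% / 70.56%), mean FD in (0, 0.5) mm, and
  additive per-site, per-edge offsets (SD 0.3) over 8 main sites plus
  2 validation-only sites.
* **Latent clinical trait.** Patients carry a 3-dimensional latent
  trait; each ADOS subscale is a rounded, clipped monotone function of
  one dimension with reliability `canonical_strength` (default 0.8,
  0.8, 0.7). Totals are forced above 7 by redrawing subscale noise.
  Controls carry no trait and no ADOS scores.
* **Severity subgroups as a mixture.** The defining premise of a
  recovery test is that distinct subgroups exist. Severe and mild
  subgroups (35% / 65%) are therefore two mixture components whose
  centers lie `subgroup_separation` (default 3) apart along the
  equi-loading direction of the latent space — severe patients are
  higher on *every* subscale dimension — with within-subgroup SD
  `latent_within_sd` (default 0.3) per dimension.
* **Edges.** 100 signal edges load on the latent dimensions (loading
  0.7, cycled across dimensions with alternating sign); 20
  severe-marker edges are shifted by `subgroup_separation` in severe
  patients; 20 mild-marker edges realize a mild > severe > control
  ordering (shifts 0.8 / 0.4); unit-SD Gaussian noise and linear
  covariate loadings complete the values on the Fisher-z scale.

Two design notes deserve emphasis because they were settled by explicit
geometry during generator construction, not by taste:

1. **Why a mixture rather than a shifted Gaussian?** With a
   unit-variance latent and an additive severe shift, the correlation
   between any canonical score and the true subgroup indicator is
   bounded near 0.85 at *any* separation, and Ward on whitened 3-D
   scores only recovers two clusters reliably once that correlation
   exceeds ≈ 0.9 (a sharp empirical threshold). Subgroup recovery with
   ARI ≥ 0.8 is then unattainable — i.e. the recovery requirement
   itself pins down the mixture reading of "planted subgroups".
2. **Why do only the leading components replicate?** Because the
   severity mixture loads on all dimensions, the latent dimensions are
   correlated, and the population canonical spectrum concentrates:
   `impliedCanCor()` computes the closed-form implied values (≈ 0.90,
   0.41, 0.34 at the defaults) that the ground truth stores. A
   consequence worth knowing: with one dominant component, η² (a
   *product* across components) can sit below its selection-aware null
   even when R₁ is overwhelmingly significant — the per-component
   permutation p-values carry the signal.

What the generator does **not** emulate: autocorrelated BOLD noise,
heavy-tailed motion artifacts, site-by-covariate interactions,
non-linear trait-edge links, and diagnosis-related covariate
confounding beyond the planted linear effects. Passing tests therefore
demonstrate correctness and calibration of the *pipeline*, not
expected effect sizes on real cohorts.

## Numerical choices

* Spearman p-values use the t-approximation on n − 2 df (n ≥ 10
  enforced); ties get average ranks; top-k ties break by edge position.
* Permutation p-values use the add-one rule (1 + #{null ≥ obs})/(1 + B);
  failed permutation iterations (rank-deficient resamples) are redrawn,
  capped at 1% of B.
* Cluster labels are deterministic given input order (`hclust` tie
  order); singleton clusters take silhouette 0; equal-mean clusters
  label the smaller one severe with a warning.
* Degenerate ADOS contrasts (zero within-cluster variance) yield an NA
  contrast with a warning rather than an abort, since the labeling
  itself remains well defined.
* Within-subject standardization uses the population SD; residualization
  is refit on the union of subjects entering each comparison
  (stratification: discovery; biomarkers: discovery + control;
  external validation: discovery + validation).

## Problem sizes used in the shipped checks

The calibration experiment uses 200 null cohorts of 120 discovery
subjects × 496 edges with B = 199 and screening at the study's
feature-to-sample ratio (k = 46 ≈ 0.3846·120; at these sizes the
threshold rule would select fewer than three edges, so the fixed-ratio
screen is applied identically to observed and permuted data, which
preserves exchangeability). Subgroup recovery runs 20 study-sized
cohorts (260/574/29 subjects, 4,371 edges, k = 100). The acceptance
script's headline pipeline run uses B = 999 and the fixed-ratio screen;
unit tests use smaller planted cohorts (120 discovery subjects, 276
edges, B ≤ 60). The reported cross-validated r under permuted labels is
computed at n = 260, where the familiar small-sample negative bias of
cross-validated correlations is negligible.

## Known limitations

* Canonical correlations reported in-sample are inflated by roughly
  (1 − R²)·k/n; recovery of planted values is therefore assessed on the
  null-adjusted scale (the same shrinkage as adj-η², with a
  fixed-selection null). The permutation machinery, not the raw R_i,
  carries the inference.
* Feature selection for prediction uses subgroup labels derived from
  the full discovery sample, mirroring the published procedure; the
  resulting optimism of the inner-sample r is a property of that
  procedure (the external validation group is the honest check).
* The site model is additive; harmonization methods addressing
  site-by-covariate interactions are out of scope.
* ADOS totals are treated as Communication + Social Interaction
  throughout; instruments scored differently must be mapped before
  ingestion.
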