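---
title: "Models and design choices in sepsismet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in sepsismet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsismet)
```

`sepsismet` analyses targeted plasma metabolomics from preterm neonates with
suspected late-onset sepsis, separating three clinical groups: controls,
systemic inflammation without sepsis (SINS), and sepsis. This vignette
explains the statistical machinery, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable implementation existed.

## The data model

Input abundances are peak-area ratios (analyte over internal standard), one
row per plasma sample, with repeated samples per subject: suspected-episode
samples plus follow-ups drawn 6–48 h later that carry the episode's final
group label. Ten clinical covariates travel with every sample — gestational
age (weeks), birthweight (g), postnatal age (days), proportion of calories
from parenteral nutrition, oxygen percentage, sex, sample source
(artery/capillary), mechanical ventilation, intraventricular hemorrhage, and
antibiotics within 24 h — along with IL-6, CRP and PCT.

## Preprocessing

Stages run in a fixed order; each stage's output satisfies the next stage's
preconditions.

1. **QC filter.** A metabolite is retained iff its pooled-QC relative
   standard deviation is below 30%, its method-blank signal below 40% of the
   QC mean, and its missingness below 20% — strict inequalities, so a
   feature sitting exactly at a threshold is removed. RSD and blank% are
   computed on the linear scale, where the assay defines them; the paper's
   text applies the missingness rule as a single study-wide threshold, so it
   is applied per feature over all study samples, not per group.
2. **Sample outliers.** The Rosner (generalized extreme studentized deviate)
   test runs on a per-sample summary of internal-standard responses
   (`is_log_mean`), with α = 0.05 and up to 5 candidates. The input
   statistic is a design choice: the method's source only states that
   internal standards were used.
3. **Derived features.** Ratios, sums and means are computed on the linear
   scale *before* log2, so the log2 of a ratio equals the difference of the
   operands' log2 values and its fold change stays interpretable. Derived
   values inherit operand missingness and are not re-subjected to QC.
4. **log2** (missing stays missing), then **QRILC**, then **autoscaling**
   (per-feature mean 0, sd 1).

### QRILC

Missingness in targeted metabolomics is concentrated below the detection
limit, so imputation assumes left-censoring rather than missingness at
random. Per sample, the observed log2 values are treated as the upper
`1 − m` fraction of a normal distribution: sorted values get plotting
positions `p_k = m + (1 − m)(k − 0.5)/n_obs`, a least-squares fit against
`qnorm(p_k)` yields μ̂ (intercept) and σ̂ (slope), and each missing entry is
drawn from `N(μ̂, tune·σ̂)` truncated above at `μ̂ + tune·σ̂·qnorm(m)`.
Observed cells are never touched. `tune` (default 1) rescales the imputation
spread; values below 1 pull the truncation limit toward μ̂ and are not
recommended. Orientation is per sample, following the reference method's
convention; the per-feature alternative can be had by transposing, but the
pipeline does not expose it because the sample is the censoring unit
(one injection, one sensitivity).

Degenerate inputs fall back to half-minimum imputation (the observed
minimum, halved on the linear scale) with a warning: a nonpositive fitted
σ̂, or a sample with under 30% of features observed, where the plotting
position fit is unreliable. Simulations in the test suite show QRILC's mean
absolute error beats minimum-value imputation *on average* under 20%
censoring; per-replicate superiority is only ~80% likely, because the
theoretical MAE margin (≈ 0.06 σ: 0.500 σ for an independent draw from the
true tail versus 0.558 σ for imputation at the censoring threshold) is of
the same order as the per-replicate sampling noise of the MAE itself.

## The mixed-model screen

Each feature is modelled on the autoscaled log2 scale as

$$y_{ij} = \beta_0 + \beta\,d_{ij} + \textstyle\sum_k \gamma_k c_{ijk} + u_i + \varepsilon_{ij},
\qquad u_i \sim N(0, \tau^2),\ \varepsilon_{ij} \sim N(0, \sigma^2),$$

with a subject random intercept absorbing repeated samples and \(d\) the
0/1 contrast code. Five contrasts are screened: Inflamed (SINS + sepsis vs
control), Sepsis (sepsis vs control + SINS), and the pairwise C_SINS, C_S,
SINS_S models. Estimates are therefore in autoscaled-SD units, while fold
changes are computed separately on the unscaled imputed log2 table as ratios
of group geometric means "prior to confounder correction" — the two scales
the study reports.

*Inference.* p-values for β use Satterthwaite-adjusted Wald t-tests. The
canonical single-feature fit (`fit_contrast_lmm()`) delegates to
`lmerTest::lmer()`. The screen (`run_screen()`) instead profiles the REML
criterion in the variance ratio λ = τ²/σ² analytically: for a random
intercept the per-cluster inverse covariance is `I − ((1−e)/n_i) J` with
`e = 1/(1 + n_i λ)`, so GLS estimates, the REML objective, and the observed
information of (σ², τ²) — hence Satterthwaite df — reduce to cluster sums
shared across all features. This is why screening 296 features takes under
a second; the test suite pins the engine to `lmerTest` output (estimates and
SEs to 1e-6, df to 1e-2). A singular fit (τ̂² = 0) is refit as ordinary
least squares and flagged, which also covers designs with one sample per
subject.

*Confounders.* A covariate enters the fixed effects if it associates with
sepsis outcome (Fisher exact for categorical, Welch t for continuous,
α = 0.05) or with any of the top 5 principal components of the autoscaled
matrix (Spearman for continuous; Welch t / one-way ANOVA for categorical) —
an automated stand-in for the source's "visual inspection by PCA".

*Multiplicity.* Benjamini–Hochberg q-values are computed within each
model/stratum over its full feature family (n = 296 at the default scale),
with the screening threshold q < 0.1; trend letters and stratified
comparisons use uncorrected p < 0.05, matching the study's dual convention.

*Trend classification.* From the three pairwise models at p < 0.05 plus
pre-correction group means: shared inflammation (C_SINS and C_S significant,
same sign, SINS_S not), progressive up/down (C_SINS and SINS_S significant,
same sign, monotone means), sepsis-specific (SINS_S and C_S significant,
C_SINS not), SINS-specific (C_SINS significant, C_S not, SINS_S either not
significant — the underpowered compact-letter pattern a/b/ab — or
significant with the opposite sign, the fully-powered pattern a/b/a). The
a/b/a extension is deliberate: a truly SINS-specific shift *must* make
SINS_S significant once power suffices, so the narrower rule would send
every well-powered SINS-specific feature to "unclassified".

*Stratified models.* The Sepsis contrast reruns within one sex, or with the
sepsis arm restricted to one pathogen type or culture outcome against all
non-sepsis samples; the stratum variable is dropped from the confounder set.
The comparator composition (all non-sepsis samples retained) is a choice the
source leaves open.

## Diagnostic modelling

The single-time-point (STP) subset keeps one sample per subject at the
moment of suspicion: the first sepsis episode's suspected sample if any,
else the first SINS episode's, with controls only from subjects never
suspected; follow-ups are never eligible. On SINS vs sepsis:

- **Univariate logistic screening** with BH correction; perfect separation
  triggers a ridge-stabilized refit and a flag.
- **Bootstrap-aggregated LASSO** (B = 100): class-stratified bootstrap
  resampling (plain resampling at n ≈ 60 frequently loses a class), an
  L1-penalized logistic fit per resample with the penalty chosen by internal
  5-fold cross-validated deviance, and out-of-bag AUC/sensitivity/
  specificity at threshold 0.5. Out-of-bag evaluation is an interpretation:
  the source's lower bootstrap-mean AUC against its reduced-model AUC
  implies a held-out estimate. The penalty uses the one-standard-error rule
  (`lambda.1se`): with the deviance minimum, per-fit models at this sample
  size carry 10–20 features and chance-correlated nulls cross the 45%
  stability threshold in essentially every run, inflating the panel well
  past the sparse-panel scale the method is meant to produce; `lambda.min`
  remains available via `lambda_rule`.
- **Stability selection**: features selected in strictly more than 45% of
  fits, by frequency. Even so, recovering 4 of 5 planted 0.8-SD features
  with at most 2 false entries succeeds only in roughly half of simulated
  replicates at n = 60 among 100 nulls — at that signal size a planted
  feature's univariate evidence (t ≈ 3) overlaps the extreme order
  statistics of 100 nulls, a limit of the scenario rather than of the
  implementation.
- **LOOCV evaluation** of nine variants (panel; IL-6, CRP, PCT; all markers;
  panel + each marker; panel + all markers): per-fold unpenalized logistic
  fits (ridge-stabilized under separation), trapezoidal rank AUC, and
  sensitivity/specificity/PPV/F1 at the threshold maximizing Youden's J on
  the out-of-fold predictions — the source reports paired metrics without
  naming a rule, and Youden is the standard default. Markers enter as
  log-scale values, autoscaled for comparability; whether the original
  analysis transformed them is unstated.
- **McNemar comparisons** of every variant against the panel: exact
  two-sided binomial on the discordant pairs when b + c < 25, else the
  continuity-corrected chi-square.

## Correlation analysis

Spearman correlations (average ranks for ties, two-sided p by the t
approximation) between panel metabolites and each inflammatory marker are
computed within SINS and within sepsis; the between-condition difference is
tested by the Fisher r-to-z statistic
\(z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}\).
The 1.06 variance inflation sometimes recommended for Spearman correlations
is off by default (`spearman_adjust`); the unadjusted statistic's type-I
error at these sample sizes stays within [0.03, 0.08] in simulation. No
multiplicity correction is applied to the correlation family, matching the
descriptive use of these profiles.

## The synthetic cohort generator

`simulate_dataset()` generates data under exactly the model the screen
assumes — that is its purpose and its main limitation. Defaults encode the
study conditions: 180 subjects split 0.48/0.21/0.31 into
control/SINS/sepsis so that, with a 0.5 follow-up probability for suspected
episodes, expected sample counts land near the study's 86/56/85; sepsis
cultures split 42:29:14 culture-negative:gram-positive:gram-negative;
confounder distributions follow the cohort table (gestational age
26.67 ± 2.07 weeks, birthweight 891.9 ± 279.45 g, postnatal age
21.19 ± 18.45 days, TPN 0.38, oxygen 30.13 ± 14.33%, male 0.599, arterial
source 0.225), with mechanical ventilation and IVH given a logistic
dependence on sepsis status because the study found them outcome-associated;
antibiotics-within-24h prevalence (0.30) is a chosen value the table does
not print. Features default to 296 (254 measured + 42 derived slots);
differential classes plant shared-inflammation, progressive (half shift in
SINS, full in sepsis), sepsis-specific, SINS-specific, sex-specific (sepsis
shift in males only) and pathogen-specific (gram-negative only) effects with
magnitudes drawn from 0.3–1.0 residual-SD units, the range of printed model
estimates; the subject intercept uses ICC 0.4 (τ² = icc/(1−icc)·σ²).
Missingness is purely left-censored at a per-feature quantile — no
missing-at-random component — because that is QRILC's stated assumption.
Inflammatory-marker shifts are set so single-marker SINS-vs-sepsis AUCs land
near 0.53–0.59, the weak range reported for CRP/IL-6/PCT. The measured
technical CV (0.1), blank fraction (0.05) and censoring severity (0.1) are
testability choices; the study does not report its assay's values.

What the generator does **not** emulate: correlation between metabolites
within pathways (features are conditionally independent given confounders
and the subject intercept), non-normal abundance distributions, batch or
injection-order drift, assay saturation at the high end, and
informative-sampling effects (who gets a follow-up is random here). Passing
tests therefore demonstrate the pipeline's statistical correctness under its
own model, not robustness to violations of it.

Every generator output is a pure function of (specification, seed);
QC-violating features are planted as labelled extras so the filter's
behaviour has ground truth.

## Numerical choices and degenerate inputs

- REML profiling runs on log λ over [1e−8, 1e3] with `optimize()` at
  tolerance 1e−10, compared against the λ = 0 boundary; ties go to the
  boundary (OLS, flagged).
- A feature with zero QC mean has an undefined RSD and auto-fails QC with a
  reason flag; a constant feature cannot be autoscaled and raises an error
  naming it.
- Fisher tables with a zero margin return p = 1 with a warning; constant
  vectors make Spearman correlations NA with a warning; |r| = 1 makes the
  r-to-z transform diverge and is an error.
- `directed_pvalue()` rejects p = 0; the screen clips at 1e−300 before
  taking logs.
- Exact-tie handling: the Youden threshold scans the observed LOOCV
  prediction values; rank AUC uses average ranks, so ties count 1/2.

## Problem sizes

The test suite validates calibration at the sizes the properties demand
while staying desk-scale: 100 replicates of the 296-feature all-null screen
at 150 subjects for FDR control, 200 replicates at 200 subjects for effect
recovery and coverage, 50 replicates of B = 100 bootstrap-LASSO runs at
n = 60 for stability selection, 2000 replicates for differential-correlation
type-I error, and single cohorts of 300–2000 subjects for generator
calibration checks. The five-contrast default-scale pipeline
(`run_all()`) completes in well under a minute on one core.
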