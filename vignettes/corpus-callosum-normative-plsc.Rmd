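---
title: "Normative W-scores and PLSC for callosal development: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative W-scores and PLSC for callosal development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnorm)
```

ccnorm analyses derived feature tables from a two-group developmental
neuroimaging design: a very preterm (VPT, born before 32 gestational weeks)
group and a full-term (FT) control group of children and adolescents, each
subject described by a clinical record (age at assessment, gestational age,
IQ and five raw neuropsychological scores, optionally a Largo socio-economic
score) and by 33 corpus callosum structural measures — 5 partition volumes
plus mean FA, MD, NDI and ODI over 7 tract segments (rostrum to splenium).
This vignette explains the two statistical procedures at the package's core,
the tunable parameters, the synthetic cohort generator used as a testbed, and
the numerical conventions and limitations a user should know about.

## Preprocessing: the analysis matrices

`build_matrices()` assembles the clinical matrix X (n × 8, or n × 9 with SES)
and the structural matrix Y (n × 33). Age, gestational age and IQ pass
through unchanged — IQ instruments (FCI for ages below 10, GAI from 10 up)
are already age-standardized on the mean-100/SD-15 scale, so residualizing
them again would remove true signal. The five raw scores with strong
developmental trends (working memory span, congruent-condition reaction time,
flanker inhibition accuracy difference, affect recognition, theory of mind)
are regressed on age at testing by simple linear OLS *within the analysed
group*, and the residuals are standardized to SD 1 (denominator n − 1). Two
choices deserve a note:

* **Within-group residualization.** Each analysis is fit within one group
  (FT, VPT, or the pooled cohort), so the age correction uses only the
  subjects entering that analysis; pooling the regression across groups would
  leak group differences into the residuals.
* **Reaction time keeps its natural sign** (larger = slower). The familiar
  reading "faster responses load with maturation" is applied when
  interpreting loadings, not by flipping the data.

Simple linear regression on age was chosen over polynomial alternatives as
the conventional reading of an age correction for these instruments; with the
6–14-year range the curvature left in these scores is modest relative to
their noise.

## Cohort-based normative modelling and W-scores

The normative model asks: *for a child of this age, what does this measure
look like in the full-term population?* The package answers it twice, in the
order the pipeline uses them:

1. **LOESS developmental trajectory** (`loess_predict()`,
   `fit_normative_model()`): a locally weighted polynomial regression of each
   measure on FT age. For a query age, the `ceiling(span * n)` nearest FT
   subjects are weighted by the tricube kernel `(1 − (d/d_max)^3)^3` and a
   degree-2 polynomial (configurable to 1) is fitted and evaluated at the
   query. The span is chosen per measure by `optimize_span()` over
   [0.05, 1.0] with Brent's bounded minimization (tolerance 1e-4).
2. **Age-bin norms and W-scores** (`compute_bin_norms()`,
   `compute_w_scores()`): FT subjects are grouped into four age bins
   (72–96.5, 96.6–122, 122.1–148, 148.1–173 months), each bin/measure gets a
   normative mean and SD (denominator n − 1), and every VPT subject receives
   `w = (value − mu_bin) / sigma_bin` for each measure: the deviation from
   normative neurodevelopment in FT-SD units.

W-scores use the **bin norms**, not the LOESS predictions; the trajectory is
retained for reporting and plots. The switch `wscore_basis = "loess"`
exposes the alternative (LOESS-predicted mean, SD of FT trajectory
residuals) for sensitivity analyses.

Numerical conventions:

* **Bin assignment** treats bins as half-open `[lo, hi)` with the last bin
  closed. The canonical bin edges as printed leave 0.1-month gaps
  (96.5 vs 96.6); the half-open convention closes them. Ages outside all
  bins are assigned to the nearest bin with a warning — never dropped.
* **Span objective.** The default objective is the in-sample sum of squared
  errors, as the normative-modelling recipe states, with leave-one-out SSE
  (`objective = "loocv"`) as the alternative. In-sample SSE decreases
  monotonically toward the smallest feasible span — at the boundary the
  local fit interpolates the data — so optimized spans under the default are
  small and the resulting curves wiggly. This is a property of the stated
  objective, not of the optimizer; users who want smooth trajectories should
  use `"loocv"` or a fixed span. Because both objectives depend on the span
  only through the neighbour count `k = ceiling(span * n)` (they are step
  functions of the span), the Brent pass is followed by an exact sweep over
  the attainable `k` values and the better point is returned.
* **Degenerate local designs.** With tricube weights the farthest of the
  `k` neighbours gets weight zero; when too few points carry positive weight
  for the polynomial degree the weighted least-squares system is solved by
  rank-revealing QR and the prediction is the (always identified) fitted
  value at the query point. Requests where `k < degree + 1` error, naming
  the span.
* **Guard rails on norms.** A bin with fewer than 2 FT subjects or a zero
  SD is an error; bins with fewer than 5 FT subjects trigger a warning,
  since norms from a handful of children are fragile.

## Partial least squares correlation

`plsc_fit()` z-scores every column of X and Y (denominator n − 1), forms the
cross-correlation matrix `R = t(Xz) Yz / (n − 1)` and takes its singular
value decomposition `R = U S t(V)`. Component k pairs a clinical salience
(column of U) with a structural salience (column of V); latent scores are the
projections `Xz U` and `Yz V`, and **loadings** (structure coefficients) are
the correlations of the original variables with their block's latent score,
bounded in [−1, 1]. Two scaling facts motivate the z-scoring: the loadings
are only correlation-like on the correlation scale, and the inertia identity
`sum(S^2) = ||R||_F^2` then ties the spectrum to the total cross-block
association. The latent-score covariance of component k equals `S_k`, the
quantity PLSC maximizes.

Inference follows the standard two-resampling recipe:

* **Permutation test of the singular values**
  (`permutation_pvalues()`, default 1000 permutations): X rows are permuted
  with Y fixed and the k-th permuted singular value compared to the observed
  one, per rank, without Procrustes rotation of the permuted subspaces. The
  p-value uses the add-one convention `(1 + count) / (1 + n_perm)`, whose
  floor at 1000 permutations is 1/1001 ≈ 0.001; components are called
  significant at p < 0.01.
* **Bootstrap stability of the loadings** (`bootstrap_loadings()`, default
  500 resamples): subjects are resampled with replacement jointly in X and
  Y; each resample's saliences are sign-aligned to the original by the
  dot-product rule per component (the Y salience flipped jointly), and the
  loadings recomputed on the resampled data, so the bootstrap SD measures
  the sampling variability of the reported statistic itself. A loading is
  **robust** when its bootstrap-z two-sided normal p-value is below 0.01
  *and* its magnitude is at least 0.4 (`robust_mask()`).

Determinism conventions: the largest-magnitude entry of each clinical
salience is forced positive (with the joint flip applied to the structural
side), which pins the sign of every reported quantity without affecting any
invariant; permutation and bootstrap streams take explicit integer seeds.
Degenerate perfect associations (bootstrap SD below 1e-12) report an
infinite bootstrap z and p = 0 rather than dividing by zero. Resamples that
produce a constant column are redrawn, at most 10 times each. The simple
per-rank permutation comparison (no Procrustes) is a stated simplification;
it is conservative for later components when the leading component is
strong, and exact for the dominant-component regime these analyses live in.

## The synthetic cohort generator

`generate_cohort()` emulates the *derived* tables the analysis consumes —
not raw MRI. Its defaults are the study conditions the pipeline targets:
39 FT and 65 VPT subjects, ages uniform on 72–173 months, gestational age
39.83 (1.33) weeks for FT (truncated to 37–42) and 29.59 (1.73) weeks for
VPT (truncated below 32), FT/VPT birth weights 3438.72 (412.05) /
1288.00 (378.62) g and Largo scores 2.89 (1.29) / 4.44 (2.55).

Each structural measure follows

```
value = baseline + slope_family * (age - 120)
        - [VPT] rate * noise_sd_family * age * (32 - ga) * sign_family
        + coupling * noise_sd_family * sign_family * z + noise
```

where `sign_family` is the maturation direction (+ for FA, NDI, volume;
− for MD, ODI), `z` is a standard-normal scalar latent "maturation" factor
per subject, and the clinical scores mix the same `z` with instrument noise
on their native scales. Values outside their legal ranges are clipped and
counted; at the defaults clipping is essentially never triggered. The
effect sizes have no published values; they were fixed once at levels a
developmental-imaging practitioner would call realistic and detectable:

* **Age slopes** of roughly +0.08 FA, −0.06 MD (1e-3 mm²/s), +0.08 NDI,
  −0.04 ODI and +150 mm³ volume per 100 months, against family residual
  SDs of 0.025, 0.03, 0.03, 0.02 and 60 mm³.
* **Latent couplings** of 0.6 (IQ), 0.5 (working memory), −0.5 (reaction
  time), 0.25–0.3 (inhibition, socio-emotional scores) on the standardized
  scale, and 0.8 family-SD on the structural side — sized for high power of
  the dominant PLSC component at n = 104.
* **Deviation rate** 0.006 family-SD per (month × week below 32), about a
  1.7-SD mean shortfall from the normative trend at the average age and
  prematurity. Two competing design targets pin this value from opposite
  sides: sign-recovery of the planted W-score trends in ≥95% of cohorts
  would need ≈0.0073 or more, while keeping the additive deviation from
  driving volumes negative (clipping in at most 1% of cohorts) needs less
  than ≈0.007. The rate honours the hard physical constraint. Notably, the
  ≥95% sign-recovery target is out of reach at *any* rate: because
  prematurity multiplies age in the deviation term, the OLS slope of W on
  age carries noise that scales with the effect itself, and its t-statistic
  is capped near 2.6 under these cohort sizes — about one to two wrong-sign
  cohorts per 50 are expected no matter how large the planted effect. The
  package reports this property honestly rather than redefining it.
* The **age–gestational-age correlation** seen in real VPT samples (about
  −0.26) is off by default to keep the generative model exchangeable;
  `age_ga_corr = TRUE` reproduces it by shifting VPT ages with prematurity.

`planted_truth()` returns the sign pattern a recovery analysis should find
(loading signs per variable, up to the joint flip both blocks share, and the
per-family W-trend signs against age and gestational age), which is what the
parameter-recovery tests assert against — never published loadings.

What the generator does *not* emulate: measurement floor/ceiling effects in
the test instruments, site or scanner batch structure, non-Gaussian tails,
missingness mechanisms, longitudinal correlation, or more than one latent
behavioural dimension. Passing recovery tests therefore show the estimator
chain is correct and well-calibrated under a faithful one-component world,
not that real data meet these assumptions.

## Problem sizes used by the test-suite

The distributional checks run at sizes chosen to make their Monte-Carlo
error small relative to the asserted margins while keeping the suite quick:
the permutation size check uses 200 independent-noise replicates of
n = 60, p = 4, q = 6 with 200 permutations each (nominal 5% ± 4%
asserted); parameter recovery uses 50 default cohorts with 200 permutations
and 200 bootstrap resamples each; the group-equality-in-law check uses 100
null cohorts with a Kolmogorov–Smirnov test at the 5% level and a 99%
binomial envelope. Fixed seeds make every one of these runs reproducible.

## Known limitations

* The FT norm sample (n = 39 across four bins) yields per-bin norms from
  roughly 8–14 children; W-scores inherit that estimation noise. The
  package warns below 5 per bin and refuses below 2.
* In-sample SSE span selection over-fits by construction (see above);
  prefer `"loocv"` when the trajectory itself matters.
* The permutation test permutes X rows only, which assumes exchangeability
  of subjects under the null; covariance structure between blocks induced by
  confounders is not protected against.
* Bootstrap sign alignment uses the per-component dot-product rule, adequate
  for a single dominant component; axis rotation among near-degenerate later
  components is not corrected (no Procrustes), so their bootstrap SDs are
  conservative.
* All analyses are cross-sectional; the "developmental trajectory" is a
  cohort-level description, not a within-child one.
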