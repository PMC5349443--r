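---
title: "deltamed: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltamed: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltamed)
```

## What the package estimates

`deltamed` asks whether serum proteins mediate the APOE ε4 allele's
association with a *latent dementia phenotype*. The phenotype, δ, is
defined as the cognitive correlates of functional status: the variance
that cognitive test scores share with everyday function. Its residual
in general intelligence, g′, is the cognitive variance unrelated to
function. The package (i) builds δ and g′ from wave-2 indicators,
(ii) scores subjects, (iii) validates the scores against clinical
diagnosis (ROC) and dementia severity (CDR sum of boxes), and (iv)
screens a wave-1 immunoassay panel for analytes whose levels transmit
part of the APOE effect onto future δ scores.

## The measurement model and its identification

The bifactor arrangement is

* `deq` (δ) loads on LMII, VRI, COWA, DST and IADL;
* `gprime` (g′) loads on the four cognitive tests only;
* the factors are orthogonal with unit variance; unique variances are
  free; indicators are standardized before fitting.

Standardizing first is a deliberate reading of "indicators not
adjusted": no *covariate* adjustment is applied at this stage, but
putting indicators on a common scale is required for comparable
loadings and stable optimization.

**A caution on identification.** With five indicators this model has a
single degree of freedom, and the allocation of cognitive common
variance between δ and g′ is pinned down only through the IADL column
of the covariance matrix. When the two loading vectors are nearly
proportional across the cognitive tests the likelihood has a flat
ridge: fits from different samples wander along it even at n = 5000
(Monte-Carlo SD of the g′ loadings ≈ 0.03–0.04). Point recovery of
individual loadings is therefore unbiased but not tight per sample;
composite scores, which aggregate over the ridge, are much more
stable. In the degenerate case where IADL is independent noise the
allocation is wholly unidentified — only the *implied
cognition–function covariance* (the product of cognitive and IADL
loadings on δ) is determined, and the tests assert exactly that.

**Factor scores.** Regression (Thomson) weights
`W = Σ(θ̂)⁻¹ Λ̂ Φ̂` are used, with Grice determinacy (the correlation
between factor and score) reported per factor; δ's determinacy on the
default synthetic world is ≈ 0.91, above the conventional 0.80 bar.
One consequence worth stating plainly: although g′ has *no loading* on
IADL, its regression-score weight for IADL is negative and nonzero —
the score subtracts function in order to purge δ from the residual
composite. Zeroing that weight would re-contaminate g′ with δ
(measured on the default world: the g′ score's correlation with true δ
rises from ≈ 0.2 to ≈ 0.6) and would destroy the empirical signature
that δ, not g′, carries the dementia signal. Rows with missing
indicators are scored by re-solving the weight system on their
observed sub-vector, which is the correct per-pattern renormalization.

Score orientation is resolved (the bifactor likelihood is invariant to
factor sign) so that higher δ scores mean better function; risk
effects are therefore negative.

## The covariance-structure engine

Models are held in RAM form (directed paths A, symmetric covariances
S, means M); implied moments are `Σ = [B S Bᵀ]` with `B = (I − A)⁻¹`.

* **Complete data.** The discrepancy `F_ML = log|Σ| − log|S| +
  tr(SΣ⁻¹) − p` is minimized with analytic gradients assembled through
  the RAM chain rule. S uses the divisor-N (maximum-likelihood)
  covariance so that the minimizer is the exact MLE and FIML with zero
  missingness reproduces it to optimizer precision; the reported
  χ² is the classic `(N−1)·F_ML`.
* **Missing data.** FIML maximizes the casewise normal likelihood,
  grouped by missingness pattern. The model χ² is the likelihood
  ratio against the saturated model, which is fit by EM; the
  independence baseline has a closed-form solution per variable.
* **Fit indices.** CMIN/DF, CFI and RMSEA in their standard forms; the
  CFI null is the independence model with free variances (and means
  under FIML). All are `NA` for saturated models rather than fabricated.
* **Optimization.** BFGS on free parameters with variances
  log-transformed for positivity. Starting values are data-driven and
  deterministic: sample moments for (co)variances and means,
  equation-wise OLS for regressions, 0.7-scaled loadings. For
  recursive path models with saturated exogenous blocks these starts
  sit at the optimum already, which is what makes screening ~100
  analytes per minute feasible. Unique variances shrinking to the
  boundary (Heywood tendency) are flagged, not hidden.
* **Standard errors.** Inverse observed information. For complete-data
  recursive path models the information is block-diagonal and the SEs
  have exact closed forms (equation-wise `σ̂²(XᵀX)⁻¹`, Wishart forms
  for moments), verified in the tests against the numerically
  differentiated Hessian used in the general case.
* **Convergence.** Relative function change below 1e-12 or a
  sample-size-scaled gradient norm below 1e-5; non-convergence flags
  the fit rather than failing silently.

## The mediation screen

All variables are standardized, so paths are on the correlation scale.
For each analyte, two simultaneous equations (with the seven covariates
— age, education, ethnicity, gender, GDS, HCY, HgbA1c — entering both
outcomes as paths, and all exogenous variables correlating freely):

* `analyte_w1 ~ c·APOE + covariates`
* `deq_w2 ~ a·APOE + b·analyte_w1 + covariates`

The indirect effect is the product `b·c` with the Sobel delta-method
z; the proportion mediated is `b·c/(b·c + a)` — the standard
product-over-total form — reported only when the indirect and total
effects agree in sign. Residualizing outcome and analyte on the
covariates before a three-variable model is available as an option
(`adjust = "residualize"`) and agrees closely with path adjustment on
complete data.

**Classification.** The class gate is `max(gate, 0.05)`: analytes with
both b and c paths significant at 0.05 enter the mediator table, and
`survives_bonferroni` records whether both clear the stricter fixed
p < 0.001 gate. This keeps near-miss mediators visible (flagged, not
hidden) while the strict gate governs the headline claim; the fixed
threshold — rather than α/m — is deliberate, with the panel size
logged for transparency. Analytes with only the b path significant are
APOE-independent δ biomarkers; the rest are unrelated. The three
classes partition the panel.

**Replication.** A seeded 50/50 split (odd subject to group 1); the
mediation model is fit simultaneously in both halves with a, b, c free
versus constrained equal, compared by a 3-df χ²-difference test.
Non-significant worsening (p > 0.05) means the mediation structure
replicates; the effect is then recomputed from the constrained fit. A
negative χ² difference is flagged as an estimation problem, never
clipped into a passing p-value.

Note one arithmetic caution inherited from the source literature: a
χ² difference of 1.9 on 3 df has p ≈ 0.59 under the χ² law; the
package computes the distributionally correct value.

## Panel QC

Fixed order, each step logged per analyte with counts so cells in =
removed + retained:

1. duplicate reads averaged; pairs differing by more than 5% of their
   mean discarded (the pair mean as denominator is symmetric and
   scale-free; averaging the survivors minimizes assay noise);
2. analytes with more than 50% LOW (below-detection) readings dropped
   — exactly 50% is retained — and remaining LOW cells imputed as
   LDD/2;
3. single-pass deletion of cells beyond 3 SD of the raw-scale mean
   (LOW resolution precedes this because LDD/2 substitution changes
   the mean and SD; the raw-versus-log placement of the pass is
   configurable, raw being the default reading of "raw data were
   inspected");
4. natural-log transform when |skewness| > 1 (the conventional
   "highly skewed" rule of thumb), then standardization;
5. residualization on dummy-coded batch, re-standardized, making
   within-batch means exactly zero.

Analytes that lose essentially all cells along the way (for example,
100% discordant duplicates) are dropped with reason `too_few_values`
rather than propagating an empty column.

## The synthetic world

The generator draws: APOE ~ Bernoulli(0.39); seven covariates with
realistic locations/scales, age–GDS and HCY–HgbA1c correlated at 0.1
(a token of the "densely intercorrelated" covariate block, not a claim
about its true structure); analyte latents `M_j = c_j·APOE_std +
noise`; `δ = a·APOE_std + Σ b_j M_j + covariate terms + residual` with
the residual chosen so δ has exactly unit variance — so configured
paths *are* the standardized truth; g′ ~ N(0,1) independent.
Indicators for each wave load on δ and g′ with fresh unique noise and
are placed on test-like scales. Diagnosis is a three-class threshold
on δ plus noise calibrated to ≈ 41/20/37% NC/MCI/AD; CDR-SB is a
truncated linear decrease in δ. Both links are stand-ins — the source
analysis treats diagnosis as a consensus label with no stated
generative mechanism — and any monotone link suffices for testing the
ROC stage.

Default structural values: direct APOE path a = −0.25; three true
mediators patterned on CRP (c = −0.15, b = 0.15), APN (−0.10, 0.145)
and AREG (−0.13, 0.15), giving single-mediator proportions mediated in
the 5–8% band; 83 δ-only analytes at b = 0.08 (so the panel jointly
explains roughly half of δ's variance, echoing the claim that most of
δ's variance is biomarker-associated, while keeping the total under
unity — a larger per-analyte b at this panel size would be
arithmetically impossible); 30 null analytes.

Default loadings put δ mainly on memory and function (LMII 0.80,
VRI 0.75, COWA 0.70, DST 0.55, IADL 0.80) and g′ mainly on
attention/working memory (0.20, 0.25, 0.40, 0.65). The distinct
patterns are a deliberate identification choice: near-proportional
loading vectors would put the generating model on the bifactor ridge
described above, making *any* estimator's recovery unstable.

Assay artifacts are measurement-layer effects: per-batch shifts enter
the measured reads (not the biologically active latent — otherwise
batch adjustment would sever the analyte's true link to δ), raw reads
are log-normal, duplicates get multiplicative CV noise, the bottom
quantile of each analyte is flagged LOW with the threshold recorded as
the LDD, a small fraction of cells is replaced by >3-SD extremes, and
cells go missing MCAR (or MAR in δ, to stress FIML) at the configured
rate.

**What a green test establishes — and what it does not.** The world is
linear-Gaussian with a binary exposure; it emulates the *statistical
structure* the analysis assumes (latent bifactor cognition, weak
analyte mediation, assay artifacts), not the marginal distributions of
real RBM analytes, real covariate demographics, attrition between
waves, or nonlinear dose–response. Passing tests mean the estimators
recover the stated world's truth and control error rates there;
they say nothing about unmodeled misspecification.

Two attenuation facts matter when reading recovery results.
Score-based paths estimate determinacy-attenuated effects: with
ρ(δ) ≈ 0.91, a true total effect of −0.27 appears as ≈ −0.25 — the
proportion mediated is unaffected because numerator and denominator
attenuate together. Assay artifacts attenuate the analyte paths
(b, c) by a few percent more; the parameter-recovery acceptance test
therefore runs with artifacts disabled, while artifact handling is
tested by the QC suite on planted counts.

## Known limitations

* No robust or ordinal estimators; no modification indices (residual
  covariances are a user-supplied list only); no bootstrap SEs in the
  screen (the Sobel z is analytic, cross-checked once against a
  percentile bootstrap oracle in the acceptance suite).
* The bifactor split is weakly identified at five indicators by
  construction; composite scores are reliable, individual g′ loadings
  are not precision quantities.
* FIML assumes missing-at-random; the MAR stress test covers
  missingness driven by modeled variables only.
* The multi-group equality test covers the split-half design; a full
  measurement-equivalence workflow (ethnicity invariance derivation)
  is out of scope.
* APOE is modeled as a standardized binary regressor inside a normal
  likelihood; its χ²-difference tests are asymptotic, and the
  split-half calibration test measures their actual level on the
  synthetic world.
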