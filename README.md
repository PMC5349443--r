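# deltamed

Screening a serum-protein panel for mediators of the APOE ε4 allele's
effect on a latent dementia phenotype.

## The problem

The latent variable δ ("dementia") is defined as the *cognitive
correlates of functional status*: the shared variance between cognitive
test performance (Logical Memory II, Visual Reproduction I, COWA, Digit
Span) and everyday function (IADL). Scored as a composite, δ separates
demented from non-demented subjects far better than general
intelligence does. Carrying an APOE ε4 allele is associated with worse
future δ scores; the open question is whether circulating proteins
(inflammatory markers among them) *mediate* that association.

`deltamed` implements that analysis end-to-end for longitudinal cohort
data with a multiplex immunoassay panel, and — because such cohort data
are not publicly deposited — ships a synthetic-cohort generator with
known ground truth so every stage is testable.

## The model

**Phenotype.** A bifactor measurement model on five wave-2 indicators:
δ (here `deq`) loads on all five, the orthogonal residual-intelligence
factor g′ loads on the four cognitive tests only; both factors have
unit variance. Regression-method weights `W = Σ(θ̂)⁻¹ Λ̂ Φ̂` turn
indicators into composite scores; Grice determinacy reports their
quality.

**Estimation.** A compact covariance-structure (SEM) engine: maximum
likelihood minimizes

    F_ML(θ) = log|Σ(θ)| − log|S| + tr(S Σ(θ)⁻¹) − p,

with χ² = (N−1)·F_ML; with missing cells, full-information ML maximizes
the casewise normal likelihood over each subject's observed sub-vector
and the χ² is the likelihood ratio against the EM-fitted saturated
model. CMIN/DF, CFI and RMSEA are computed against the independence
model.

**Mediation.** For each QC-passed analyte, simultaneous equations on
standardized variables (seven covariates adjusted by paths):

    analyte_w1 ~ c·APOE + covariates
    deq_w2     ~ a·APOE + b·analyte_w1 + covariates

Indirect effect `b·c`, Sobel z = b·c / √(b²se_c² + c²se_b²), proportion
mediated `b·c/(b·c + a)`. Analytes sort into three classes — mediator,
APOE-independent δ biomarker, unrelated — with a fixed p < 0.001
Bonferroni-style gate and split-half replication (paths a, b, c
constrained equal across random halves; 3-df χ²-difference test).

**Panel QC.** Duplicate reads discarded when they differ by more than
5% of their mean; analytes that are majority below-detection dropped,
remaining LOW readings imputed as LDD/2; single-pass 3-SD outlier
deletion; log transform of skewed analytes; standardization; batch
residualization on dummy-coded batch.

## Worked example

```r
library(deltamed)

cfg <- cohort_config(seed = 1)      # the default synthetic world
sim <- generate_cohort(cfg)         # cohort + raw panel + ground truth
qc  <- qc_panel(sim$panel)          # analyte QC
dm  <- build_deq(sim$cohort)        # bifactor phenotype + scores
print(dm)
#> delta_model (wave 2 bifactor): 3385 subjects scored
#>   chi-square = 0.97 (df = 1), CFI = 1.000, RMSEA = 0.000
#>   determinacy: deq = 0.914 , gprime = 0.775
#>   AUC (AD vs NC): deq = 0.964 (0.956-0.972), gprime = 0.605
#>   r(deq, CDR-SB) = -0.825

fit_base_model(sim$cohort, dm$scores)
#> base_model (n = 3385 ):
#>   APOE -> deq    : -0.259 (SE 0.016), p = 3.88e-59
#>   APOE -> gprime : -0.063 (SE 0.017), p = 0.000246

scr <- screen_panel(sim$cohort, dm$scores, qc, gate = 0.001, seed = 1)
print(scr)
#> mediation_screen: 116 analytes | gate = 0.001 | class alpha = 0.05
#>   mediators: 7 (APN, AREG, CRP, DLT15, DLT25, DLT3, DLT4)
#>     APN: indirect = -0.0118, z = -4.40, mediates 4.6%
#>     AREG: indirect = -0.0119, z = -4.39, mediates 4.6%
#>     CRP: indirect = -0.0166, z = -5.06, mediates 6.4%
#>     DLT15: indirect = 0.0043, z = 2.49, mediates NA [does not survive Bonferroni]
#>     ...
#>   APOE-independent delta biomarkers: 80
#>   unrelated: 29
```

Reading the output: the phenotype scores discriminate AD from normal
controls (AUC ≈ 0.96) and track dementia severity (r ≈ −0.83 with CDR
sum of boxes); carrying an ε4 allele predicts a ~0.26 SD lower future
δ score after covariate adjustment; the screen recovers the three
planted mediators (the CRP-, APN- and AREG-like analytes survive the
p < 0.001 gate), each carrying a mid-single-digit percentage of the
APOE effect. A handful of δ-only analytes brush the 0.05 class gate by
chance — as expected for 80 analytes screened at α = 0.05 — and are
flagged as not surviving Bonferroni; the rest land in the
APOE-independent and unrelated classes.

A command-line wrapper with subcommands `generate`, `qc`,
`build-delta`, `screen`, `summarize`, `run-all` is installed at
`inst/cli/deltamed`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic cohort from the given seed and runs
the whole pipeline — QC, phenotype construction, base model, mediation
screen with split-half replication — logging the headline quantities
(fit, determinacy, AUC, CDR correlation, APOE path, surviving
mediators) to stderr and writing the results JSON to `--out`.

## Vignette

`vignettes/deltamed-methods.Rmd` documents the model and its
assumptions, what the synthetic world does and does not emulate, the
numerical choices in the SEM engine, and known limitations.
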