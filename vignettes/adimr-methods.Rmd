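---
title: "Methods: Mendelian randomisation of adiposity on depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation of adiposity on depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adimr)
```

## The causal question and the study design

Conventional logistic regression of depression on adiposity cannot
distinguish causation from confounding (socioeconomic position, smoking,
illness) or reverse causation (depression changing appetite and weight).
Mendelian randomisation uses genetic variants associated with adiposity as
instrumental variables: genotypes are fixed at conception and randomised at
meiosis, so — under the instrumental-variable assumptions — the
genetically-predicted component of adiposity is free of those biases.

`adimr` implements both arms of such a study. The *two-sample* arm needs
only GWAS summary statistics for the exposure and the outcome from
non-overlapping samples. The *one-sample* arm needs individual-level data:
a genetic risk score (GRS) is built within the cohort and used as a single
instrument in two-stage regression. Because the individual-level data this
design targets are access-restricted, the package ships a synthetic cohort
generator whose structure mirrors the assumed data-generating process, so
every estimator can be validated against known truth.

## The synthetic cohort generator

For individual $i$ with sex $s(i)$ and region $r(i)$:

$$G_{ij} \sim \mathrm{Binomial}(2, \mathrm{maf}_j), \qquad
Z_i = \sum_j \gamma_{j,s(i)} G_{ij} + a U_i + e_i$$

$$\mathrm{logit}\, P(Y_i = 1) = \beta_0 + \theta X^{std}_i +
\theta_2 (X^{std}_i)^2 + \sum_j \delta_j G_{ij} + b U_i + \alpha_{r(i)}$$

where $U_i \sim N(0,1)$ is a shared confounder, $X^{std}$ is the
empirically standardised latent exposure, and the observed exposure is
$\mu_X + \sigma_X X^{std}$ on a BMI-like scale. The residual SD is chosen
so the latent exposure has approximately unit variance, making $\theta$
exactly the log-odds per 1-SD of exposure in the generated cohort —
the estimand every estimator targets. Pleiotropy is introduced through the
direct effects $\delta_j$ (zero for valid instruments).

Default parameters are the package's statement of the emulated study
conditions, fixed once:

- cohort size 100,377 (3398 expected depressive-symptom cases under the
  baseline logit $\mathrm{logit}(3398/100377)$), 56.9% female;
- ten regions, five urban, with configurable log-odds intercepts;
- exposure scale 23.7 (SD 3.5) kg/m², the BMI distribution of a middle-aged
  East Asian cohort;
- causal effect $\theta = \ln(0.81)$ per SD, quadratic $\theta_2 = 0$;
- per-variant effects equal within sex and scaled so the genetic score
  explains 1.5% of exposure variance in males and 3.1% in females — the
  sex asymmetry observed for BMI scores in this population;
- 100 variants by default (a simulation choice: real instrument sets for
  BMI run to several hundred variants, but the generator's statistical
  behaviour is governed by total variance explained, not variant count);
- modest positive confounding ($a = 0.25$, $b = 0.15$), enough to separate
  observational from genetic estimates in the direction seen in practice;
- CIDI-style items: cases endorse at least one of four trigger items
  (marginal endorsement probabilities 0.951, 0.436, 0.253, 0.301 among
  cases, matching the reported case item frequencies) and draw each of
  seven short-form symptoms with probability 0.30, so roughly a fifth of
  symptom cases cross the "at least 3 of 7" major-depression threshold.
  The item marginals are free parameters of the generator: the phenotype
  definitions constrain only the derivation rule, not the item
  distribution.

What the generator deliberately does **not** emulate: linkage
disequilibrium between variants (variants are independent), imputation
uncertainty (dosages are hard calls, though all consumers accept fractional
dosages in $[0,2]$), relatedness (the "unrelated" derivation-subset flag is
drawn independently per individual), and measured-covariate confounding
(the PCs are pure noise columns). Passing tests therefore validate the
estimators' statistical behaviour under the assumed model, not robustness
to population structure or cryptic relatedness in real data.

## Harmonisation decisions

Effect-allele alignment flips the outcome beta and mirrors its allele
frequency when the allele labels are swapped; allele pairs that neither
match nor swap are excluded, never rescued by strand-complement guessing.
Palindromic-variant risk is handled by the minor-allele-frequency window
filter instead: variants whose outcome-side MAF lies strictly inside
(0.45, 0.55) are removed. The bounds are strict — a variant at exactly
0.45 is retained — following the literal "greater than / less than"
definition of the window. MAF is computed from the outcome dataset because
the window is defined in the outcome ancestry. Every input variant ends up
either retained or in a machine-readable exclusion log with exactly one
primary reason (`missing_in_outcome`, `allele_mismatch`, `maf_window`,
`discordant_raising_allele`, `named_snp`), applied in that order, so
sensitivity-analysis exclusion counts are reproducible.

## Two-sample estimators: numerical choices

- **Wald ratio SE** uses the first-order delta method
  ($se_Y/|\hat\beta_X|$), which makes the IVW weighted mean *exactly* the
  zero-intercept weighted regression of outcome on exposure betas — an
  identity the test suite asserts to 1e-10. The second-order SE (adding
  $\hat\beta_Y^2 se_X^2/\hat\beta_X^4$) is available as an option.
- **Fixed vs random effects**: the default reports fixed-effects IVW
  unless Cochran's Q has p < 0.05, in which case the multiplicative
  random-effects scaling $\sqrt{\max(1, Q/(k-1))}$ is applied. The floor
  at 1 prevents an "underdispersed" fit from shrinking the SE below the
  fixed-effects value.
- **MR-Egger** orients all pairs so exposure betas are positive (flipping
  both members of a pair jointly) before fitting, which is what makes the
  intercept interpretable as average directional pleiotropy; its SEs use
  the same dispersion floor.
- **WM/PWM**: the median interpolates the ratio at standardised cumulative
  weight 0.5, $s_j = (\sum_{k \le j} w_k - w_j/2)/\sum w$. The PWM penalty
  multiplies each weight by $\min(1, 20\,p_j)$ — the published constant,
  exposed as an argument — so any variant whose heterogeneity p-value
  exceeds 0.05 is untouched. A variant extreme enough for its penalised
  weight to underflow to zero is dropped from the penalised median.
  Standard errors are parametric-bootstrap SDs (default 1000 seeded draws
  resampling both betas from their sampling normals).
- All p-values are two-sided normal, matching the 1.96-factor confidence
  intervals the estimates are reported with.

## GRS construction

The trait is rank-inverse-normal transformed (Blom offset,
$(r - 3/8)/(n + 1/4)$, average ranks for ties; the offset choice is ours —
alternatives differ negligibly at cohort sizes) within sex, since the
coding and weighting regressions are sex-stratified. Each variant's coded
allele is its trait-raising allele from the joint (all variants
simultaneously) per-sex regression; when the sexes disagree, the sex with
the larger absolute effect decides and both sexes use that coding.

Weights are *cross-fitted*: the unrelated derivation subset is split into
K = 100 seeded random blocks (balanced to within one member), and each
block's members are scored with coefficients from the joint regression —
dosages plus 12 principal-component covariates, coefficients of the latter
discarded — fitted with that block left out. This prevents any
individual's phenotype from influencing their own weights, which would
otherwise bias IV estimates toward the observational association.
Individuals outside the derivation subset are scored with
full-derivation-subset weights; this fallback is an assumption (the design
does not specify how related individuals are scored) and is recorded in
the weights object. Variants with cohort MAF < 0.01 are excluded before
weighting.

## One-sample estimation

The two-stage estimator substitutes the stage-1 fitted exposure into a
logistic outcome model. Model-based stage-2 SEs ignore stage-1
uncertainty; with a strong GRS instrument the understatement is small, but
null-calibration coverage can fall slightly below 95% — the test suite
asserts ≥ 90% coverage over 500 null replicates, and a seeded
nonparametric bootstrap SE is available where exactness matters.
Per-1-SD scaling uses the exposure SD of the full analysis sample, not the
stratum, so stratum estimates share a unit. Estimation runs within
sex × region strata; fixed-effects inverse-variance pooling produces the
all/male/female × both/urban/rural groups, with
$I^2 = \max(0, (Q - df)/Q) \cdot 100$ and Fisher z contrasts between sexes
and between settings. Strata whose logistic fit hits separation or
non-convergence are dropped and logged rather than silently pooled, as are
(optionally) strata with case prevalence below 1%.

## Control-function non-linear MR

Stage 1 is the same linear regression of exposure on GRS and covariates;
stage 2 adds the stage-1 residual to a logistic model in the exposure and
its square. The residual enters linearly only — the minimal control
function. The exposure is mean-centred within stratum before squaring to
reduce collinearity between $x$ and $x^2$; reported linear coefficients
are back-transformed to the raw scale ($\beta_1^{raw} = \beta_1 - 2m\beta_2$,
delta-method SE), and the quadratic coefficient is centring-invariant. The
non-linearity test is the quadratic term's Wald test. Fitted curves are
evaluated with pointwise variances from the coefficient covariance
(model-based, observed-information); grid points outside the observed
exposure range are flagged as extrapolation.

## Observational comparators

Per-SD odds ratios standardise by the full-sample exposure SD (hence are
invariant to affine rescaling). BMI categories use half-open intervals
[18.5, 24), [24, 28), [28, ∞): the printed clinical definitions
("18.5–23.9", "24–27.9", "≥ 28") leave rounding gaps at 23.9–24 and
27.9–28, which we read as one-decimal rounding artefacts and close so
every value is classified. Underweight individuals are excluded from all
binary category contrasts, and each category is compared to the normal
reference with other categories dropped from the fit.

## Significance conventions

Findings at p < 0.05 are tiered "tentative"; the corrected tier uses
p < 0.025 for two-sample results (two trait groups) and p < 0.013 for
one-sample results (four trait-by-setting groups). The tier is a
deterministic function applied by the pipeline to every result row.

## Validation problem sizes

The replicate suites in the package's tests run at the sizes the designs
prescribe: null calibration with 500 replicates (two samples of 20,000
with 20 instruments for IVW; 20,000 individuals with 50 variants for the
two-stage estimator), pleiotropy behaviour with 200 (Egger intercept
recovery under InSIDE) and 100 (30% invalid instruments) replicates at
20,000 per sample, and non-linearity recovery with 100 + 100 replicates at
n = 50,000. The simulated quadratic effect in the recovery suite is
$\theta_2 = 0.08$ log-odds per SD², chosen by a design-stage power
calculation to give near-certain sign recovery at that sample size.
Estimator-focused replicate suites instrument with the generative (true)
weights, isolating the estimator under test from GRS-construction noise;
cross-fitting correctness is validated separately by exact leave-block-out
recomputation.

## Known limitations

- No LD-aware instrument pruning, proxy lookup, or strand-complement
  rescue; inputs are assumed pre-pruned and same-strand.
- Mode-based estimators, MR-PRESSO, multivariable MR and reverse-direction
  MR are out of scope by design.
- Predictor-substitution SEs are approximate (see above); the
  control-function curve bands use model-based covariance.
- The synthetic generator's independence assumptions (no LD, no
  relatedness) mean test results bound estimator correctness, not
  real-data robustness.
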