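---
title: "Bi-directional Mendelian randomization of BMI and serum testosterone: models and methods"
author: "BiDirMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional Mendelian randomization of BMI and serum testosterone: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiDirMR)
```

## The scientific question

Obese men tend to have low serum testosterone, but observational
epidemiology cannot say which way the causal arrow points: adiposity may
suppress the hypothalamic--pituitary--gonadal axis, low testosterone may
promote fat accumulation, or shared factors (age, smoking, illness) may
drive both. Mendelian randomization (MR) breaks the tie by using genetic
variants as instruments. Because alleles are assigned at conception,
a risk score built from BMI-associated variants is (i) associated with
BMI, (ii) independent of lifestyle confounders, and (iii) plausibly
related to testosterone only *through* BMI. Under these instrumental
variable (IV) assumptions the ratio of the score's association with the
outcome to its association with the exposure estimates the causal
effect. Running the analysis in both directions -- a polygenic BMI score
against testosterone and a testosterone score against BMI -- separates
"obesity lowers testosterone" from "testosterone protects against
obesity".

BiDirMR implements this full analysis chain for multi-cohort studies of
men: score construction with explicit allele harmonization, Z-score
standardization, instrument validation, Wald-ratio and two-stage least
squares (2SLS) estimation, SHBG-conditioned variants, an
independent-instrument pleiotropy split, inverse-variance meta-analysis
alongside pooled individual-level analysis, clinical-units translation,
and analytic power. A synthetic multi-cohort generator with a known
structural model makes every stage testable end to end without access
to individual-level cohort data.

## Working scale: covariate-adjusted Z-scores

All estimation operates on standardized residuals. BMI is natural-log
transformed (its distribution is right-skewed; a Shapiro--Wilk
statistic on the raw values is attached as a diagnostic only), then each
trait is regressed by OLS on its adjustment set and the residuals are
scaled to unit variance:

* models with ln BMI as outcome adjust for age, smoking and
  site/cohort;
* models with testosterone (or SHBG) as outcome additionally adjust for
  time of blood sampling.

`standardizePhenotype()` enforces the contract exactly: residual mean 0
and SD 1 to 1e-8, orthogonality to every covariate, categorical
covariates as indicators, complete-case handling of missing covariates,
and loud failures on rank-deficient adjustment sets or degenerate fits.
Cohort-level analyses standardize within cohort; pooled analyses
standardize once over the pooled sample with cohort indicators in the
model. Both paths are exposed because the combination of per-cohort
estimates (meta-analysis) and the pooled fit act as mutual consistency
checks.

## Genetic risk scores

The unweighted score is the count of trait-oriented alleles (the
BMI-*increasing* or testosterone-*decreasing* allele is always the
effect allele; weights are therefore non-negative). The weighted score
is $\sum_i w_i g_i$ with per-allele weights from external GWAS. With
`rescale = TRUE` the weighted sum is multiplied by $M/\sum_i w_i$ ($M$ =
number of contributing variants), which puts it on the allele-count
scale; a 97-variant score then averages near $2\bar p \times 97 \approx
90$ alleles, matching how such scores are usually tabulated. This
transform is a reconstruction of a common convention, not a published
formula, and IV ratios are invariant to any positive affine rescaling
of the instrument (a tested property), so nothing downstream depends on
it.

Missing-data policies are explicit. Sporadic missing dosages default to
`impute_eaf` (a missing entry contributes its Hardy--Weinberg
expectation, ploidy x EAF), which leaves the score mean unbiased under
missingness-completely-at-random; `omit` is available and records the
per-individual shortfall. A variant absent from a cohort's matrix
entirely is omitted *without* rescaling by default -- the cohort's score
mean then sits visibly lower, the behaviour seen when one cohort is
genotyped for 96 of 97 variants -- with an opt-in proportional rescale.
X-linked variants in males are hemizygous and contribute dosage in
[0, 1]; since coding conventions differ between pipelines, an option
doubles them onto the [0, 2] scale for sensitivity analysis.

Harmonization is a first-class, testable operation: `dosage`, the
counted allele, and the annotated allele pair travel together in the `MRCohort`
container; `harmonizeDosages()` flips any variant counted on the other
allele (g to ploidy - g) and is idempotent, and the generator's
`scrambleAlleles()` utility produces deliberately mis-oriented (but
information-equivalent) matrices so the round trip can be asserted
exactly.

## Instrument validation

`diagnosticsReport()` reproduces the standard MR validation battery:

* the score--exposure association with its incremental $R^2$ (the
  outcome is already residualized, so this is a single-predictor fit);
* instrument strength $F = (n-2)R^2/(1-R^2)$, the single-instrument
  form consistent with that $R^2$;
* confounder balance: the score regressed on each candidate confounder,
  p-values uniform under validity;
* effect modification (score x age, score x smoking, score x other
  trait product terms) and a quadratic term for non-linearity;
* a per-variant scan with nominal and Bonferroni flags, the denominator
  being the number of polymorphic variants tested (identical to the
  fixed "0.05/97" convention when all variants are present and
  polymorphic).

## Causal estimation

`waldRatio()` computes $\hat\beta_{IV} = \hat\beta_{GY}/\hat\beta_{GX}$
with the first-order delta-method standard error
$|\hat\beta_{IV}|\sqrt{(se_{GY}/\hat\beta_{GY})^2 +
(se_{GX}/\hat\beta_{GX})^2}$ (the $\hat\beta_{GY}=0$ case reduces to
$se_{GY}/|\hat\beta_{GX}|$), treating numerator and denominator as
independent. Normal-approximation intervals are the default because the
instruments here are strong (F well above 100 at full study size);
Fieller limits are available behind a flag and agree closely in that
regime. `tsls()` is the primary one-sample estimator: stage one
regresses the exposure Z-score on the instrument (plus any extra
covariates), stage two the outcome on the fitted exposure, with the
standard 2SLS variance (residuals formed with the observed exposure, so
the generated-regressor correction is built in; homoskedastic classical
form by default, HC0 behind `robust = TRUE`). With a single instrument
and no covariates the 2SLS point estimate equals the Wald ratio to
numerical precision -- an identity the tests assert at 1e-10.

First-stage strength is policed: below F = 10 the fit warns, below
F = 1 it refuses. In the orchestrated multi-cohort run, a small cohort
whose first stage falls below the hard floor is dropped from the
cohort-level meta-analysis with a message (the pooled fit always uses
everyone); this keeps a 400-person cohort's uninformative ratio from
destabilizing a forest plot while leaving the primary pooled estimate
untouched.

Sensitivity analyses mirror the design of the original study:

* **SHBG conditioning** (`adjustedIV()`): the SHBG Z-score joins both
  stages (or testosterone does, when SHBG is the outcome), separating a
  direct effect on testosterone from one mediated by its binding
  protein. An all-missing adjustment phenotype marks the analysis
  skipped rather than failing.
* **Independent-instrument split** (`instrumentSplit()`): the lead
  locus versus a weighted score on the remaining variants, each used
  alone, with a two-sample z test on the difference (independent
  standard errors). Agreement (difference p > 0.05) argues against a
  single pleiotropic locus driving the result.
* **Observational-versus-IV comparison** (`obsVsIV()`): a Hausman-type
  z statistic on the variance difference $se_{IV}^2 - se_{obs}^2$,
  floored at $10^{-6} se_{IV}^2$ with a warning in the boundary case
  where the IV estimate is nominally the more precise. The original
  analysis does not name its test; this classic form is our
  reconstruction and is labelled as such.

### Clinical translation

`translateToPercent()` chains exact unit conversions: ratio (SD T per
SD ln BMI) x SD(T)/SD(ln BMI) x (ln(25) - ln(30)), divided by the
predicted testosterone at BMI 30 and scaled to percent. The prediction
model behind `predictedTestosterone()` is the pooled OLS of raw
testosterone on ln BMI plus the adjustment covariates held at their
sample means, which for a linear model reduces to
$\bar T + b_{\ln BMI}(\ln 30 - \overline{\ln BMI})$. With pooled
moments like SD(T) = 1.6 ng/ml, SD(ln BMI) = 0.15 and predicted T of
4.2 ng/ml, a causal ratio of -0.25 translates to roughly a 10--13%
testosterone gain for a BMI reduction from 30 to 25 kg/m^2; the exact
figure depends on the cohort moments used, which is why the function
takes them as explicit arguments.

## Combining cohorts

`fixedMeta()` uses inverse-variance weights $1/se^2$ and reports
Cochran's Q, its p-value and $I^2 = \max(0, (Q-(k-1))/Q)$.
`randomMeta()` is DerSimonian--Laird: the method-of-moments
$\hat\tau^2 = \max(0, (Q-(k-1))/(\sum w - \sum w^2/\sum w))$ and
weights $1/(se^2+\hat\tau^2)$; when $Q \le k-1$ it collapses onto the
fixed-effect result exactly. `modelSelect()` encodes the decision rule
of moving to random effects when the Q test rejects at 0.05 -- the
commonly implied but rarely stated convention; the alpha is an
argument. REML and Hartung--Knapp refinements are deliberately out of
scope at k = 5; the closed-form DL estimator is the era-appropriate
choice, and the test suite cross-checks both models against `metafor`
to 1e-10. `pooledAnalysis()` is the individual-level counterpart
(concatenated cohorts, cohort indicators in the adjustment), pooling on
the variant intersection when a cohort lacks a variant.

## Power

`ivPower()` evaluates the standard analytic power of IV regression with
a continuous outcome,
$\Phi\!\big(\sqrt{nR^2}\,|\beta| - z_{1-\alpha/2}\big)$: the expected
Wald z of the IV estimate shifted by the two-sided critical value,
keeping the upper rejection tail (so the null returns $\alpha/2$).
At n = 7446 and $\beta$ = 0.30 SD/SD it gives 95% at $R^2$ = 1.9% and
98% at $R^2$ = 2.5%, which is the justification for adopting this form;
whether a one- or two-sided convention was originally intended is not
documented, and the adopted form matches both printed values.
`halfEffectPower()` evaluates the same formula at $\beta/2$ as the
standard guard against the true causal effect being weaker than the
confounded observational slope. `empiricalPower()` validates the
formula by Monte-Carlo over full pipeline replicates.

## The synthetic-data generator

`simulateStudy()` emulates a five-cohort study of 7446 men (cohort
sizes 929, 1682, 1912, 427, 2496) with per-cohort BMI, testosterone,
SHBG, age and smoking moments stored in `defaultCohortProfiles()`. The
structural model is linear-Gaussian on the standardized scale -- the
analysis operates entirely on Z-scores, so only second moments matter --
and phenotypes are then mapped to native units (ln BMI to a
moment-matched lognormal; testosterone, SHBG and age affinely, floored
just above zero so positivity invariants hold; the floor touches well
under 1% of draws at the default profiles).

With $S_B$, $S_T$ the centered weighted score contributions, $A$, $M$,
$H$ standardized age, smoking and sampling time, and $L$ a latent
SHBG factor:

$$\mathrm{lnBMI}_z = S_B + a_B A + s_B M + \varepsilon_1$$
$$T_z = \beta_c\,\mathrm{lnBMI}_z - S_T + a_T A + s_T M + c_T H +
\lambda L + \varepsilon_2$$
$$\mathrm{SHBG}_z = \lambda L + \gamma_B\,\mathrm{lnBMI}_z +
\varepsilon_3$$

Residual variances are solved so every standardized trait has unit
variance, which makes $\beta_c$ exactly the causal effect in SD(T) per
SD(ln BMI) -- the scale on which the estimators report -- and gives the
parameter-recovery tests an unambiguous truth.

Default parameter choices, made once on realism grounds:

* `betaCausal = -0.25`: the causal-effect scale the analysis is
  designed to detect.
* instrument targets `r2GrsBmi = 0.019`, `r2GrsT = 0.025`:
  `simulateVariants()` rescales drawn weights so
  $\sum_i \mathrm{ploidy}_i\, p_i(1-p_i) w_i^2$ equals the target
  exactly at the drawn frequencies. Weight dispersion is gamma-shaped
  with coefficient of variation about 0.35, and the lead BMI locus is
  then boosted to a 15% share of the score's explained variance with
  EAF 0.42 -- the FTO-like dominance that makes a one-locus-versus-rest
  split workable, while keeping the weighted and unweighted scores'
  rank correlation above 0.9 as in real hit lists. With three
  testosterone variants, one is X-linked and they carry the rsIDs of
  the known testosterone loci.
* confounders `confAgeBmi = 0.10`, `confAgeT = -0.25`,
  `confSmokeBmi = -0.10`, `confSmokeT = 0.10`, `confTimeT = -0.05` (SD
  units): age and smoking affect both traits (testosterone declines
  with age, smokers run somewhat higher testosterone and lower BMI),
  and testosterone declines over the morning sampling window. The
  magnitudes are not published quantities; they are fixed at values
  that make covariate adjustment consequential without dominating the
  variance budget.
* `shbgTCorr = 0.51`: the shared latent component reproduces SHBG
  explaining about 26% of testosterone variance; `shbgBmiCoef = -0.15`
  gives the BMI score a secondary SHBG association. Binding chemistry
  is deliberately not modelled -- only the adjustment phenomenology.
* `heterogeneitySd = 0` by default; positive values spread the causal
  slope across cohorts for heterogeneity-recovery tests.
* sensitivity knobs, all off by default: `bmiScoreAgeInteraction`
  (score x age term), `pleiotropyEffect` (a direct path from the lead
  BMI variant to testosterone, violating exclusion),
  `mediatedBySHBG` (routes the whole causal path through SHBG), and
  MCAR `missingRate`.

Genotypes are drawn binomially at each EAF, independent of everything
else -- the defining property the confounder-balance tests verify.
There is no linkage disequilibrium, no Hardy--Weinberg violation and no
population stratification: the instruments are modelled as the
independent variants the analysis assumes. Passing tests therefore
demonstrate correctness of the estimators under the assumed structural
model, not robustness to the ways real cohorts violate it (cryptic
relatedness, assay batch effects, selection); those failure modes are
outside the generator's scope by design.

## Numerical choices and problem sizes

Seeds parameterize every stochastic routine, and identical seeds
reproduce outputs bit-identically (per-cohort seeds derive from the
study seed and the cohort's position). Simple regressions use closed
forms checked against `lm()` at 1e-10; 2SLS solves both stages by QR.
The Shapiro--Wilk diagnostic subsamples deterministic quantiles above
the test's 5000-value limit rather than touching the RNG stream.
Monomorphic variants are excluded from scan denominators; constant
covariates are dropped (pooled-sample code paths then work unchanged on
single cohorts); rank-deficient adjustment sets abort with the
collinear columns named.

Test-suite problem sizes are chosen to keep the full run under about
ten minutes while leaving Monte-Carlo error well inside the asserted
bands: moment checks at n = 50,000--200,000; estimator calibration at
the full n = 7446 with 500 replicates per true effect (the replicates
use a 12-variant instrument at the same R^2 targets -- instrument
strength, not variant count, is what the estimator sees); power and
split calibrations at a few hundred replicates of smaller cohorts. The
orchestrated pipeline tests run a scaled five-cohort study of 2500 men
with a 5% instrument so that every per-cohort first stage stays
comfortably above the weak-instrument floor.

## Known limitations

* Cohort-level published results (the observational -0.30 pooled slope,
  the published Table 2 coefficients, the 82% observational I^2, the
  consortium look-up) depend on the real individual-level data and are
  not reproduced here; the package validates the *methods* against a
  generator with known truth instead.
* The delta-method Wald ratio treats numerator and denominator as
  independent; the one-sample 2SLS estimator, which handles the
  covariance correctly, is the primary route and the two are asserted
  to agree in the single-instrument case.
* Estimands are linear SD-per-SD effects; non-linear MR and
  binary-outcome power are out of scope.
* The minimal VCF dialect stores the counted allele as ALT and carries
  weights/EAF in INFO; it round-trips dosages exactly but does not
  preserve which allele the external GWAS called "effect" when a
  variant was stored mis-oriented. The TSV interchange format is
  lossless.
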