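---
title: "Risk stratification for colorectal cancer screening with crcrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification for colorectal cancer screening with crcrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrisk)
library(dplyr)
```

## The model

`crcrisk` studies how far modifiable lifestyle factors, family history, and
common susceptibility variants can stratify colorectal cancer (CRC) risk in
an average-risk screening population. The statistical backbone is a
multivariate logistic regression of case status in a frequency-matched
case-control design:

$$\operatorname{logit} P(\text{case}) =
  \alpha + \beta_E \cdot \text{ERS} + \beta_F \cdot \text{FH} +
  \beta_G \cdot \text{GRS} + \gamma \cdot \text{PS}$$

* **ERS** counts six modifiable binary risk factors (high alcohol, obesity,
  no leisure physical activity, low vegetables, high red meat, NSAID/ASA
  non-use). Smoking is recorded but excluded: its effect vanishes once the
  other factors are in the model. Family history is kept out of the ERS
  because it is not modifiable; it enters as its own term.
* **GRS** is the additive count of risk alleles over a 21-SNP panel. The
  one X-linked variant is coded 0/0.5/1 so that its contribution has the
  same scale in both sexes; hemizygous males (0/1 copies) are coded 0/0.5.
  Because the published per-SNP effects are similar, the unweighted count
  is the default; `compute_grs()` also supports published-GWAS log-odds
  weights and weights refit to the data (`refit_grs_weights()`).
* **PS**, the propensity score, is the logit-scale prediction of case
  status from the design variables (age, sex, education, recruiting
  centre, three ancestry components, plus age×sex and centre×sex
  interactions). Frequency matching on age, sex and region makes those
  variables uninformative for risk but a source of selection imbalance;
  carrying their combined prediction as one continuous covariate absorbs
  that imbalance. Age enters linearly by default (5-year bands are
  available via `age = "bands"`); education is an unordered small factor.

The headline relative risk score condenses the fitted model into
$$RS = OR_E^{\,\text{ERS}-\bar e} \cdot OR_F^{\,\text{FH}} \cdot
       OR_G^{\,\text{GRS}-\bar g},$$
with defaults $OR_E = 1.36$, $OR_F = 2.25$, $OR_G = 1.07$, $\bar e = 3$,
$\bar g = 22$, so the reference profile has RS = 1. The parameters and both
reference values are configurable through `risk_score_params()`; rounded
odds ratios are the default, which is why a profile such as (ERS = 6,
FH = 1, GRS = 28) evaluates to $1.36^3 \cdot 2.25 \cdot 1.07^6 \approx 8.49$
rather than any value derived from unrounded coefficients.

## Discrimination: the stratified cross-validated AUROC

Predictive accuracy is the area under the ROC curve, computed by rank
concordance (Mann–Whitney, ties = 1/2). To keep the matched design from
flattering or penalising the model, the AUROC is computed **within
propensity quintiles** and averaged with weights proportional to each
quintile's case count (`ps_stratified_auroc()`). Quintile boundaries are
sample quantiles of the pooled propensity score; ties at a boundary fall
into the lower stratum. A stratum without cases gets weight zero (warning);
a stratum with cases but no controls aborts, since its AUROC is undefined.

`cv_auroc()` wraps this in 5-fold cross-validation with folds stratified by
case status: the model is refit on four folds and held-out subjects are
scored by the fitted linear predictor; pooled held-out scores feed the
stratified AUROC. Confidence intervals are percentile bootstrap over
subject-level resamples (default 200), re-running the full cross-validation
with re-randomized folds per resample. Cross-validation removes the
optimism of the resubstitution estimate (`apparent_auroc()`), a property
the test-suite verifies over replicates. `cumulative_auroc_curve()` orders
variables by individual AUROC and adds them one at a time, reproducing the
usual "contribution ladder" display.

## From relative to absolute risk

`project_cumulative_risk()` multiplies registry cumulative risks by the
relative score, capping at 100 per 100 with a flag. Multiplying cumulative
risks (rather than hazards) by odds ratios is the simple, transparent
convention adopted here; it is only approximately valid at high RS or high
baseline risk, which the cap makes visible. `risk_advancement_age()`
inverts the (strictly increasing) projected curve by monotone
piecewise-linear interpolation to find the age at which an elevated-risk
subject reaches the cumulative risk of the average subject at a reference
age; under exponentially rising incidence $CR(a) = c e^{ka}$ the
advancement is exactly $\log(RS)/k$, which the tests use as a closed-form
oracle.

Screening operating characteristics come from `screening_performance()`
("test-positive" means RS at or above the cutoff) and `ppv_by_age()`
applies Bayes' theorem with the age-range prior taken as the difference of
cumulative risks across the range (conditional survival to the range start
is deliberately ignored — an approximation, stated here once). Priors are
therefore *unconditional* decade risks; the conditional variant would
divide by the probability of reaching the decade cancer-free, which for
CRC's small cumulative risks changes little.

The packaged incidence table
(`inst/extdata/incidence_spain_synthetic.csv`) is a **synthetic** fixture
shaped like Spanish registry curves — exponential rise from age 50,
male above female, lifetime cumulative risk ~10 per 100 (men) and ~5
(women), and a 5-year doubling time around age 50. It is a constructed
stand-in, not registry data; any table with columns
`sex, age, cum_risk_per100` can be supplied.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes:

* a population pool (default 3× the target cohort size) with ages drawn
  from 5-year bands 25–85 weighted towards 50–85, 62% male, 12 regions,
  education sampled independently, and three standard-normal ancestry
  components (computing real ancestry components from genotypes is out of
  scope — the generator emits them directly);
* six independent Bernoulli risk factors at the control prevalences of the
  source study (15.6%, 6.9%, 38.5%, 69.2%, 40.9%, 27.3%), family history
  at 12.14%, smoking at 56.5%; raw lifestyle variables are synthesized on
  the correct side of each cut-off so `derive_risk_factors()` recovers the
  latent indicators exactly;
* Hardy-Weinberg genotypes at the panel's risk-allele frequencies
  (Binomial(2, p); Binomial(1, p) for the X variant in males);
* outcomes from the logistic model with $\beta_E = \log 1.36$,
  $\beta_F = \log 2.25$, $\beta_G = \log 1.07$ and intercept −2.8 (about
  30% cases in the pool);
* 1336 cases sampled among those with at least one matchable control, and
  controls frequency-matched within sex × region × 5-year band at the
  target 2.05:1 ratio (sampling without replacement; leftover controls
  discarded; a stratum with cases but no eligible controls is an error in
  `frequency_match()` itself).

Under this calibration the model's true linear predictor has variance
$\approx 0.21$, which implies an AUROC of about
$\Phi(\sigma/\sqrt 2) \approx 0.63$ — so the generator reproduces both the
fitted odds ratios and the published-scale discrimination without any
tuning knob beyond the stated inputs.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, correlations among lifestyle factors (reported as absent), direct age
or sex effects on the outcome (these act only through matching and the
propensity score; a direct effect can be added via the configuration),
informative missingness (masking is MCAR via `inject_missing()`), and
measurement error or recall bias. Passing tests therefore show the
pipeline's correctness under the stated generative assumptions, not that
real interview data meet them.

### A note on the allele-frequency calibration

The default panel frequencies imply a control mean GRS of about 18, while
the study population this design mirrors reported a control mean of 22.1
alleles — panel frequencies published by discovery GWAS need not match a
specific target population. Both calibrations are supported: the panel
`raf` column can be overridden, and the RS reference $\bar g$ is a
parameter. The package deliberately asserts neither as "the truth"; the
defaults stay with the only printed per-SNP frequencies, and analyses that
need RS = 1 at the cohort average should re-centre `risk_score_params()`
at the observed means (as the README example does).

## Numerical and design choices

* Imputation (`impute_missing()`) is deterministic single imputation:
  continuous variables get the expected value from an OLS regression on
  age, sex and case status fitted to complete cases (the predictor set is
  an argument); whole-valued variables with ≤ 3 levels (binary flags,
  genotypes) get the modal category, ties towards the smaller value.
  Observed cells are never altered.
* Wald 95% confidence intervals throughout; crude 2×2 odds ratios use the
  Woolf logit interval and refuse zero cells rather than apply a
  continuity correction.
* Logistic fits are `stats::glm`; complete separation is detected and
  aborted with diagnostics rather than returning divergent coefficients.
  Rank-deficient propensity designs drop the offending columns with a
  warning (e.g. centre×sex in a single-sex centre); single-level factors
  are absorbed into the intercept.
* Bootstrap: 200 subject-level resamples, percentile interval. The
  count and interval type are choices, not fixed by the method.
* All randomness is seed-controlled; regenerating a cohort with the same
  seed is bit-identical.

## Problem sizes

The test-suite works at reduced scale chosen to exercise the statistics,
not the hardware: interval-coverage checks run 100 replicates of
300-case/600-control cohorts; odds-ratio recovery averages 20 replicates at
the full 1336/2744 design; the discrimination check uses a single
5000/10,000 cohort; `scripts/acceptance.R` uses 20 replicates at 1336/2744
plus one 10,000/20,000 cohort for the cross-validated AUROC.

## Example

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_config(), seed = 1) |>
  derive_risk_factors() |>
  impute_missing() |>
  compute_ers() |>
  compute_grs() |>
  compute_rs() |>
  add_propensity()

tidy(fit_risk_model(cohort))
cv_auroc(cohort, n_boot = 50, seed = 2)

proj <- project_cumulative_risk(synthetic_incidence_table(), c(0.5, 1, 2, 5))
autoplot(proj)
```

## Limitations

Beyond the generator simplifications above: the case-control design cannot
estimate absolute risk internally (hence the external incidence table); the
propensity adjustment assumes the matched design is captured by the listed
design variables; cumulative-risk × OR projection overstates risk where the
product approaches the cap; and the 21-SNP panel predates the much larger
sets of susceptibility loci now known, so the genetic contribution here is
a lower bound on what a modern panel could add.
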