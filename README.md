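# crcrisk

Risk stratification for colorectal cancer (CRC) screening from combined
environmental and genetic risk factors.

Population CRC screening is triggered by age alone, yet individual risk
varies widely with lifestyle, family history, and common susceptibility
variants. `crcrisk` implements a full case-control risk-stratification
pipeline around three scores:

- **ERS** (environmental risk score): the count, 0–6, of modifiable binary
  risk factors — high alcohol intake (>4 standard units/day in men, >2 in
  women), obesity (BMI ≥ 30 kg/m²), no leisure-time physical activity
  (0 MET h/week), low vegetable intake (≤ 200 g/day), high red-meat intake
  (> 65 g/day), and no regular NSAID/aspirin use.
- **GRS** (genetic risk score): the unweighted count of risk alleles across
  a 21-SNP susceptibility panel, with the single X-linked variant
  (rs5934683) coded 0/0.5/1; weighted variants (published GWAS weights or
  weights refit to the data) are also available.
- **RS** (relative risk score):
  `RS = OR_E^(ERS − ē) · OR_F^FH · OR_G^(GRS − ḡ)` with defaults
  OR\_E = 1.36, OR\_F = 2.25, OR\_G = 1.07, ē = 3, ḡ = 22, so that the
  population-average profile has RS = 1.

Because case-control studies frequency-match controls to cases, every risk
model is adjusted by a **propensity score**: the logit-scale prediction of
case status from age, sex, education, recruiting centre, three genetic
ancestry components, and the age×sex and centre×sex interactions.
Discrimination is measured with a propensity-quintile, case-weighted AUROC
under 5-fold cross-validation with bootstrap confidence intervals. Finally,
relative scores are projected onto registry cumulative incidence to obtain
absolute risk curves, risk-advancement periods (how many years earlier a
high-risk subject reaches the average-risk benchmark), screening
sensitivity/specificity/likelihood ratios, and Bayes-theorem predictive
values by age range.

Raw interview and genotype data of this design are not public, so the
package ships a **synthetic cohort generator**: frequency-matched
case-control cohorts (sex × region × 5-year age band) with binary risk
factors at realistic control prevalences, Hardy-Weinberg genotypes at the
panel allele frequencies, and outcomes drawn from a logistic model with the
odds ratios above. Every downstream stage is therefore testable end to end.

## Worked example

```r
library(crcrisk)

cohort <- simulate_cohort(cohort_config(), seed = 2024) |>
  derive_risk_factors() |>
  impute_missing() |>
  compute_ers() |>
  compute_grs() |>
  add_propensity()

fit <- fit_risk_model(cohort, terms = c("ers", "family_history", "grs"))
tidy(fit)
#> # A tibble: 5 × 7
#>   term           estimate std.error statistic  p.value conf.low conf.high
#>   <chr>             <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 (Intercept)       0.215    0.467      -3.29 9.97e- 4   0.0863     0.537
#> 2 ers               1.34     0.0337      8.65 5.02e-18   1.25       1.43
#> 3 family_history    1.97     0.0966      7.03 2.09e-12   1.63       2.38
#> 4 grs               1.05     0.0119      4.34 1.43e- 5   1.03       1.08
#> 5 ps                3.04     0.587       1.89 5.82e- 2   0.962      9.62
```

The fitted odds ratios recover the generator's calibration (1.36 per
environmental factor, 2.25 for family history, 1.07 per risk allele) within
sampling error on this single 1336-case / 2744-control cohort.

```r
cv_auroc(cohort, k = 5, n_boot = 50, seed = 1)
#> # A tibble: 1 × 6
#>   method           estimate conf.low conf.high     k n_boot
#>   <chr>               <dbl>    <dbl>     <dbl> <dbl>  <dbl>
#> 1 cv_ps_stratified    0.604    0.592     0.625     5     50
```

The cross-validated, propensity-stratified AUROC of the full model sits
near 0.6 at this cohort size — modest discrimination, in line with
published CRC risk models (the large-cohort value under this calibration is
about 0.63).

Screening-policy quantities follow from the relative risk score. With the
default panel allele frequencies this generator's cohorts average about 2
risk factors and 18 alleles, so here the RS is re-centred at those
averages:

```r
cohort <- compute_rs(cohort,
                     params = risk_score_params(ers_reference = 2,
                                                grs_reference = 18))
perf <- screening_performance(cohort, c(0.5, 1, 2, 5))
perf
#> # A tibble: 4 × 7
#>   cutoff sensitivity specificity positive_lr negative_lr ...
#> 1    0.5      98.5          3.19        1.02       0.469
#> 2    1        65.5         49.5         1.30       0.697
#> 3    2        15.9         92.5         2.14       0.908
#> 4    5         0.150       99.9         1.34       1.000

risk_advancement_age(synthetic_incidence_table(), rs = 2, reference_age = 50)
#> # A tibble: 2 × 5
#>   sex       rs reference_age equivalent_age advancement_years
#> 1 female     2            50             45                 5
#> 2 male       2            50             45                 5

ppv_by_age(synthetic_incidence_table(), perf,
           decades = c("50-59", "70-79")) |>
  dplyr::filter(cutoff == 2)
#> # A tibble: 4 × 7
#>   sex    decade cutoff sensitivity specificity  prior     ppv
#> 1 female 50-59       2        15.9        92.5 0.0045 0.00957
#> 2 female 70-79       2        15.9        92.5 0.022  0.0459
#> 3 male   50-59       2        15.9        92.5 0.009  0.0190
#> 4 male   70-79       2        15.9        92.5 0.044  0.0895
```

A subject with twice the average relative risk reaches, at age 45, the
cumulative risk an average subject reaches at 50 — a 5-year screening
advancement on the packaged synthetic incidence curves. The positive
predictive value of a RS ≥ 2 classification rises with the age-range prior
(here from ~1% of men aged 50–59 to ~9% of men aged 70–79).

Plot helpers: `autoplot()` on a projection, `plot_score_distribution()`,
`plot_cumulative_auroc()`, `plot_ppv_by_age()`.

A thin command-line wrapper lives at `inst/cli/crcrisk.R`
(`simulate`, `score`, `project`, `ppv` subcommands).

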