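# Default calibration of the synthetic case-control cohort generator.
# Factor prevalences are control prevalences of the source study; the true
# odds ratios are the fitted multivariate effects the generator reproduces.
n_cases: 1336
n_controls: 2744
factor_prevalences:
  alcohol_high: 0.1556
  obese: 0.0685
  no_physical_activity: 0.3852
  low_vegetables: 0.6917
  high_red_meat: 0.4093
  no_nsaid_asa: 0.2730
fh_prevalence: 0.1214
smoking_prevalence: 0.5645
or_per_factor: 1.36
or_fh: 2.25
or_per_allele: 1.07
baseline_logit: -2.8
age_bands: [25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80]
age_band_weights: [1.2, 1.2, 1.2, 1.2, 1.2, 12.25, 12.25, 12.25, 12.25, 15, 15, 15]
sex_ratio_male: 0.62
n_regions: 12
education_levels: [primary, secondary, university]
education_probs: [0.5, 0.3, 0.2]
pool_factor: 3
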