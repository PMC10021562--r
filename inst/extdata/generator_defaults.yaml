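# Default data-generating configuration for the synthetic study.
#
# Choice side: level utilities on the effects-coded (zero-sum) scale.
# Published point estimates are used where the study reports them; levels
# the study leaves unprinted are synthetic fill-ins chosen once to satisfy
# the within-attribute zero-sum constraint (and, for money, to be monotone
# increasing in the amount). Survey side: marginal distributions calibrated
# to the descriptive statistics of the quantitative sample; outcome slopes
# are the published odds ratios on the log scale, intercepts calibrated to
# sample prevalences at covariate means. The drugs-model hunger slope is a
# synthetic stand-in (set large: in the study every recent drug user also
# reported hunger, so no finite estimate exists).
choice_model:
  n_respondents: 242
  opt_out_constant: 0.522
  level_utilities:
    condom_use: [0.679, 0.031, -0.710]
    money: [-0.5, -0.1, 0.2, 0.4]
    when_money_given: [0.132, 0.0, -0.132]
    relationship_length: [0.300, -0.379, -0.176, 0.255]
    partner_age: [0.212, -0.012, -0.200]
  # per-coefficient SDs of normal random taste heterogeneity; all zero
  # gives homogeneous (MNL) preferences
  sigma: 0.0
covariate_model:
  age: {mean: 39.2, sd: 9.58, min: 18}
  registered: {prob: 0.40}
  difficulty_350_bill: {prob: 0.85}
  income_monthly: {medianlog: 3000, mean: 3468}
  months_in_industry: {median: 90, mean: 110}
  months_per_year: {mean: 7.4, sd: 2.67, min: 0, max: 12}
  who5_total: {mean: 16.2, sd: 4.2}
  hunger_flag: {prob: 0.15}
  hiv_knowledge: {p_low: 0.47, p_mid: 0.28, p_very_high: 0.25}
  ever_used_drugs: {prob: 0.537}
outcome_model:
  covariates: [age, registered, difficulty_350_bill, months_in_industry,
               months_per_year, poor_wellbeing, hunger_flag, hiv_knowledge]
  ever_tourist_sex:
    intercept: 1.423
    slopes: [-0.0222, -0.3106, -0.0408, 0.0050, -0.0987, -0.1427, -0.0440, -0.0284]
  condom_last_sex:
    intercept: 0.888
    slopes: [-0.0202, -0.2865, -0.3653, -0.0010, -0.1109, -0.1520, 0.0853, 0.1371]
  sti_12m:
    intercept: -0.936
    slopes: [-0.0523, -1.3943, 0.6366, -0.0010, -0.0030, -1.0876, 1.5014, 0.1389]
  alcohol_30d:
    intercept: -2.347
    slopes: [0.0218, -0.8627, -0.1154, -0.0030, 0.1231, -0.0672, 0.2747, -0.0419]
  drugs_3m:
    # fitted only among ever-users of drugs
    intercept: 6.124
    slopes: [-0.0834, -0.8416, 0.9014, -0.0101, -0.1851, 1.2399, 2.0, 0.1062]
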