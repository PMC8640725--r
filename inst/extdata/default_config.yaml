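# Demo configuration for the synthetic multimorbidity cohort generator.
# Omitted fields (covariate prevalences, ground-truth intensities, condition
# preference) take the package defaults; see ?cohort_config.
n_patients: 2000
seed: 1
study_window: ["2005-04-01", "2020-05-02"]
registration:
  median: 4.2          # target observed median follow-up, years
  iqr: [1.8, 8.4]      # target follow-up IQR (sets the lognormal spread)
  frac_at_origin: 0.36 # fraction already registered at the study start
initial_state_probs: [0.76, 0.15, 0.05, 0.04]
preference:
  p_same: 0.7          # cluster stickiness of newly acquired conditions
include_prior_onsets: true
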