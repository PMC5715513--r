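# Calibrated generator scenario: full-scale hospital cancer registry with
# pre-cleaning duplicate/invalid rows and the default mechanism mix.
n_patients: 25827
duplicate_patient_count: 2083
invalid_date_count: 22
female_fraction: 0.495
age_mean: 61.6
age_sd: 15.7
true_event_rate: 0.0078
history_coding_rate: 0.0145
mimic_rate: 0.0078
testonly_coding_rate: 0.0053
ruleout_suspected_rate: 0.0088
ruleout_true_prob: 0.07
background_imaging_rate: 0.02
same_day_duplication_prob:
  definite: 0.54
  suspected: 0.66
seed: 20070101
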