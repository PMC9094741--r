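# Packaged cohort presets. Each top-level key is a preset; any field of
# pwv_preset() may be overridden here. Values mirror the package defaults.
athletes:
  "n": 129
  age_mean: 56
  age_sd: 11
  age_range: [35, 86]
  sbp_mean: 128
  sbp_sd: 15
  dbp_mean: 78
  dbp_sd: 8
  bmi_mean: 24.0
  bmi_sd: 3.5
  sex_ratio: 0.6822
  hr_mean: 61
  hr_sd: 11
agbresa:
  "n": 24
  age_mean: 33
  age_sd: 9
  age_range: [18, 70]
  sbp_mean: 125
  sbp_sd: 11
  dbp_mean: 70
  dbp_sd: 7
  bmi_mean: 24.3
  bmi_sd: 2.1
  sex_ratio: 0.6667
  hr_mean: 62
  hr_sd: 9
single_subject:
  "n": 1
  age_mean: 55
  age_sd: 0
  age_range: [55, 55]
  sbp_mean: 125
  sbp_sd: 0
  dbp_mean: 70
  dbp_sd: 0
  bmi_mean: 24
  bmi_sd: 0
  sex_ratio: 1
  hr_mean: 60
  hr_sd: 0
  map_sd: 0
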