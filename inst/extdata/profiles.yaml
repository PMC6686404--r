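communityA:
  'n': 1261
  community: communityA
  age_mean: 71.4
  age_sd: 5.3
  age_min: 60.0
  age_max: 92.0
  prop_female: 0.567
  baseline:
  - 25.4
  - 31.4
  - 38.4
  - 51.4
  age_slope: 0.601
  person_sd: 9.69
  tilt_sd: 1.5
  ear_sd: 4.0
  resid_sd:
  - 7.0
  - 4.0
  - 2.5
  - 5.5
  p_asym: 0.036
  asym_min: 25.0
  asym_max: 45.0
  seed: 1
communityB:
  'n': 532
  community: communityB
  age_mean: 76.5
  age_sd: 10.2
  age_min: 60.0
  age_max: 104.0
  prop_female: 0.654
  baseline:
  - 20.2
  - 26.2
  - 32.2
  - 45.2
  age_slope: 0.601
  person_sd: 15.57
  tilt_sd: 1.5
  ear_sd: 4.0
  resid_sd:
  - 7.0
  - 4.0
  - 2.5
  - 5.5
  p_asym: 0.0953
  asym_min: 25.0
  asym_max: 50.0
  seed: 2
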