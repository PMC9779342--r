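outcome: fev1_z
singles:
- age
- height
- ses_med
- ses_high
categories:
  genetic:
  - snp01
  - snp02
  - snp03
  - snp04
  - snp05
  - snp06
  - snp07
  - snp08
  - snp09
  - snp10
  - snp11
  - snp12
  - snp13
  - snp14
  - snp15
  - snp16
  - snp17
  - snp18
  - snp19
  - snp20
  obesity:
  - bmi_fu1
  - bmi_fu2
  - low_activity
  smoking:
  - current_smoking
  - former_smoking
  - ets_work
  - ets_home
  - packyears
  air_pollution:
  - urban_residence
  - no2
  - nox
  - pm10
  - pm25
  - pm_coarse
  - pm25_abs
  - traffic_load
  - inv_dist_major
var_types:
  ses_med: binary
  ses_high: binary
  snp01: snp
  snp02: snp
  snp03: snp
  snp04: snp
  snp05: snp
  snp06: snp
  snp07: snp
  snp08: snp
  snp09: snp
  snp10: snp
  snp11: snp
  snp12: snp
  snp13: snp
  snp14: snp
  snp15: snp
  snp16: snp
  snp17: snp
  snp18: snp
  snp19: snp
  snp20: snp
  low_activity: binary
  current_smoking: binary
  former_smoking: binary
  ets_work: binary
  ets_home: binary
  urban_residence: binary
single_groups:
  SES:
  - ses_med
  - ses_high
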