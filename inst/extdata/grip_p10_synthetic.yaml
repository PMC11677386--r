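# SYNTHETIC normative handgrip table: age/sex-specific 10th-percentile
# values (kg) with a plausible adult decline. Replace with a real
# normative centile table (e.g. from a population reference study)
# before clinical use. Age bands are [age_min, age_max).
rows:
  - {sex: 1, age_min: 50, age_max: 55, p10: 34}
  - {sex: 1, age_min: 55, age_max: 60, p10: 32}
  - {sex: 1, age_min: 60, age_max: 65, p10: 30}
  - {sex: 1, age_min: 65, age_max: 70, p10: 27}
  - {sex: 1, age_min: 70, age_max: 75, p10: 24}
  - {sex: 1, age_min: 75, age_max: 80, p10: 21}
  - {sex: 1, age_min: 80, age_max: 91, p10: 18}
  - {sex: 0, age_min: 50, age_max: 55, p10: 21}
  - {sex: 0, age_min: 55, age_max: 60, p10: 20}
  - {sex: 0, age_min: 60, age_max: 65, p10: 18}
  - {sex: 0, age_min: 65, age_max: 70, p10: 17}
  - {sex: 0, age_min: 70, age_max: 75, p10: 15}
  - {sex: 0, age_min: 75, age_max: 80, p10: 13}
  - {sex: 0, age_min: 80, age_max: 91, p10: 11}
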