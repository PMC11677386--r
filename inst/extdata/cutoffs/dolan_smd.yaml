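name: dolan_smd
biomarker: l3_smd
units: HU
citation: "Dolan et al., muscle radiodensity thresholds conditional on BMI, both sexes"
rules:
  - {bmi_max: 25, threshold: 34}
  - {bmi_min: 25, threshold: 32}
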