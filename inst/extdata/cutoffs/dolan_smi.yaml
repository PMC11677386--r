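name: dolan_smi
biomarker: smi_ct
units: cm^2/m^2
citation: "Dolan et al., CT skeletal muscle index thresholds conditional on sex and BMI"
rules:
  - {sex: 1, bmi_max: 25, threshold: 45}
  - {sex: 1, bmi_min: 25, threshold: 53}
  - {sex: 0, bmi_max: 25, threshold: 39}
  - {sex: 0, bmi_min: 25, threshold: 41}
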