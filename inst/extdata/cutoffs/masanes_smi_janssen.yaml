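name: masanes_smi_janssen
biomarker: smi_janssen
units: kg/m^2
citation: "Masanes et al. (Spanish reference), BIA skeletal muscle index by sex"
rules:
  - {sex: 1, threshold: 8.31}
  - {sex: 0, threshold: 6.68}
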