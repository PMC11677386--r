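name: european_smi_janssen
biomarker: smi_janssen
units: kg/m^2
citation: "European (EWGSOP2/GLIM) BIA skeletal muscle index by sex"
rules:
  - {sex: 1, threshold: 7.00}
  - {sex: 0, threshold: 5.50}
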