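name: dreco_rf_mt
biomarker: rf_mt
units: mm
citation: "DRECO study (de Luis et al.), rectus femoris thickness by sex; note the male threshold prints below the female one in the source"
rules:
  - {sex: 1, threshold: 9.66}
  - {sex: 0, threshold: 10.4}
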