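name: vanvugt_smi_synthetic
biomarker: smi_ct
units: cm^2/m^2
citation: "Placeholder stub for externally tabulated sex-specific SMI thresholds (Van Vugt et al. appendix table)"
note: >
  SYNTHETIC placeholder values. The original thresholds are published in
  an appendix table not bundled here; replace this file with the real
  table before clinical use. The engine is fully generic, so replacing
  the file changes nothing else.
rules:
  - {sex: 1, threshold: 37.0}
  - {sex: 0, threshold: 28.0}
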