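# Machine-readable registry of the body-composition prediction
# equations. Units name the convention each equation expects; the R
# adapters perform the conversions from the package's canonical storage
# (height m, thicknesses mm).
shen_mm:
  output: "whole-body muscle mass (kg)"
  form: "(0.166 * l3_sma + 2.142) * 1.06"
  inputs: {l3_sma: "cm^2"}
mourtzakis_ffm:
  output: "fat-free mass (kg)"
  form: "0.30 * l3_sma + 6.06"
  inputs: {l3_sma: "cm^2"}
janssen_mm:
  output: "whole-body muscle mass (kg)"
  form: "5.102 + 0.401 * (height^2 / resistance) + 3.825 * sex - 0.071 * age"
  inputs: {height: "cm", resistance: "ohm", sex: "0=female,1=male", age: "years"}
kanellakis_ffm:
  output: "fat-free mass (kg)"
  form: "12.299 + 0.164 * weight + 7.287 * sex - 0.116 * (rz / height) + 0.365 * (xc / height^2) + 21.570 * height"
  inputs: {weight: "kg", sex: "0=female,1=male", rz: "ohm", xc: "ohm", height: "m"}
kotler_ffm:
  output: "fat-free mass (kg)"
  form: "0.88 * ((height^2.24 / impedance^0.63) / 37.63) + 0.16 * weight - 3.96"
  inputs: {height: "cm", impedance: "ohm", weight: "kg"}
fischer_sma:
  output: "estimated L3 muscle area (cm^2)"
  form: "-54.0 + 21.0 * sex + 0.4 * weight + 0.6 * height + 15.0 * quad_mt"
  inputs: {sex: "0=female,1=male", weight: "kg", height: "cm", quad_mt: "cm"}
newmodel_sma:
  output: "estimated L3 muscle area (cm^2)"
  form: "-74.04 + 12.03 * quad_mt + 0.56 * weight + 0.70 * height + 18.86 * sex"
  inputs: {quad_mt: "cm", weight: "kg", height: "cm", sex: "0=female,1=male"}
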