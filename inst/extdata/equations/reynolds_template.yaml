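# Reynolds-style 10-year CHD risk equation: STRUCTURAL TEMPLATE ONLY.
# Placeholder (zero) coefficients — substitute the published Reynolds Risk
# Score values (which add hsCRP and family history to the traditional
# factors) before use.
name: reynolds_chd_10y_template
form: cox_survival
baseline_survival: 0.97   # placeholder S0; replace with the published value
terms:
  - variable: age
    transform: identity
    coefficient: 0.0
  - variable: sbp
    transform: natural_log
    coefficient: 0.0
  - variable: tc
    transform: natural_log
    coefficient: 0.0
  - variable: hdl
    transform: natural_log
    coefficient: 0.0
  - variable: hscrp
    transform: natural_log
    coefficient: 0.0
  - variable: smoker
    transform: binary
    coefficient: 0.0
  - variable: family_history_chd
    transform: binary
    coefficient: 0.0
centering:
  sbp: 125
  tc: 5.0
  hdl: 1.3
  hscrp: 1.0
citation: >
  Replace coefficients with the published Reynolds Risk Score values and
  cite the source here.
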