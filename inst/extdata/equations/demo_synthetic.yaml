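# SYNTHETIC demonstration equation. The coefficients are invented, plausible
# values chosen so the equation produces non-degenerate risks on the
# package's synthetic cohorts (older age, smoking, diabetes, high SBP/TC and
# low HDL raise risk). Not a published risk score; for examples and tests.
name: demo_synthetic_chd_10y
form: cox_survival
baseline_survival: 0.92
terms:
  - variable: age
    transform: identity
    coefficient: 0.05
  - variable: male
    transform: binary
    coefficient: 0.4
  - variable: smoker
    transform: binary
    coefficient: 0.55
  - variable: diabetes
    transform: binary
    coefficient: 0.6
  - variable: sbp
    transform: identity
    coefficient: 0.012
  - variable: tc
    transform: natural_log
    coefficient: 1.1
  - variable: hdl
    transform: natural_log
    coefficient: -0.85
  - variable: tg
    transform: natural_log
    coefficient: 0.45
centering:
  age: 50
  sbp: 122
  tc: 5.2
  hdl: 1.0
  tg: 1.8
citation: synthetic demonstration values shipped with lipidcvd
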