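# Framingham-style 10-year CHD risk equation: STRUCTURAL TEMPLATE ONLY.
# The coefficient values below are PLACEHOLDERS (all zero) — replace them,
# the baseline survival and the centering values with the published ones
# from the original Framingham general cardiovascular risk profile before
# use. The evaluator is variant-agnostic: any published variant with this
# Cox-survival structure can be expressed here.
name: framingham_chd_10y_template
form: cox_survival
baseline_survival: 0.95   # placeholder S0; replace with the published value
terms:
  - variable: age
    transform: natural_log
    coefficient: 0.0
  - variable: tc
    transform: natural_log
    coefficient: 0.0
  - variable: hdl
    transform: natural_log
    coefficient: 0.0
  - variable: sbp
    transform: natural_log
    coefficient: 0.0
  - variable: smoker
    transform: binary
    coefficient: 0.0
  - variable: diabetes
    transform: binary
    coefficient: 0.0
centering:
  age: 50
  tc: 5.0
  hdl: 1.3
  sbp: 125
citation: >
  Replace coefficients with those of the published Framingham 10-year CHD
  risk function (sex-specific variants exist; pick the one matching your
  cohort and cite it here).
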