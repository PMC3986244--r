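# D:A:D-style HIV-specific 10-year CHD risk equation: STRUCTURAL TEMPLATE
# ONLY. Placeholder (zero) coefficients — substitute the published D:A:D
# values before use. The log-rate form models risk = 1 - exp(-exp(L) * t);
# cumulative antiretroviral exposure enters as years-of-exposure identity
# terms (per-year coefficients), the D:A:D structure.
name: dad_chd_10y_template
form: log_rate
horizon: 10
terms:
  - variable: age
    transform: identity
    coefficient: 0.0
  - variable: male
    transform: binary
    coefficient: 0.0
  - variable: smoker
    transform: binary
    coefficient: 0.0
  - variable: diabetes
    transform: binary
    coefficient: 0.0
  - variable: family_history_chd
    transform: binary
    coefficient: 0.0
  - variable: sbp
    transform: identity
    coefficient: 0.0
  - variable: tc
    transform: identity
    coefficient: 0.0
  - variable: hdl
    transform: identity
    coefficient: 0.0
  - variable: years_pi_exposure      # cumulative protease-inhibitor years
    transform: identity
    coefficient: 0.0
  - variable: years_nrti_exposure    # cumulative NRTI years
    transform: identity
    coefficient: 0.0
centering:
  age: 45
  sbp: 120
citation: >
  Replace coefficients with the published D:A:D CHD risk equation values and
  cite the source here.
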