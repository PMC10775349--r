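# Desk-scale steering file: linear-quadratic true model
# (alpha = 0.25 /Gy, beta = 2 /Gy^2) across the Berkson error scenarios,
# classical error fixed at 20%/20%.
name: linear-quadratic-berkson-scan
truth:
  alpha: 0.25
  beta: 2
form: linear-quadratic
scenarios:
  - {name: b0_b0,   sigma_unshared_berkson: 0,   sigma_shared_berkson: 0,
     sigma_shared_classical: 0.2, sigma_unshared_classical: 0.2}
  - {name: b20_b20, sigma_unshared_berkson: 0.2, sigma_shared_berkson: 0.2,
     sigma_shared_classical: 0.2, sigma_unshared_classical: 0.2}
  - {name: b20_b50, sigma_unshared_berkson: 0.2, sigma_shared_berkson: 0.5,
     sigma_shared_classical: 0.2, sigma_unshared_classical: 0.2}
  - {name: b50_b50, sigma_unshared_berkson: 0.5, sigma_shared_berkson: 0.5,
     sigma_shared_classical: 0.2, sigma_unshared_classical: 0.2}
methods: [regression_calibration, mcml, bma, fma]
n_meta: 100
m_sub: 100
n_cases: 250
seed: 77125
output_dir: results
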