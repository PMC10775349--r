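# Desk-scale steering file: linear true model (alpha = 3 /Gy), zero
# Berkson error, shared and unshared classical error 20%.  Scale up with
# `--scale paper` (n_meta = 500, m_sub = 1000).
name: linear-zero-berkson
truth:
  alpha: 3
  beta: 0
form: linear
scenarios:
  - name: b0_b0_c20_c20
    sigma_shared_berkson: 0
    sigma_unshared_berkson: 0
    sigma_shared_classical: 0.2
    sigma_unshared_classical: 0.2
methods: [unadjusted, regression_calibration, mcml, bma, fma]
n_meta: 100
m_sub: 100
n_cases: 250
seed: 20240313
mcmc:
  n_chains: 2
  n_burnin: 1000
  n_keep: 1000
fma:
  k: 100
  symmetric_sd: true
output_dir: results
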