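# Example pipeline configuration for copdsemi::run_pipeline().
# A 52-week two-arm synthetic trial with a treatment effect delaying
# exacerbation onset and sparse log-logistic dropout, fitted with the
# integrated log-logistic two-state model.

seed: 1

simulation:
  n_per_arm: 150
  study_length: 364
  family: loglogistic
  alpha1: 1.34
  alpha2: 2.97
  theta1: 150
  theta2: 10
  treatment_beta1: 0.31
  sigma2: 0.1
  dropout: true

model:
  family: loglogistic
  covariates1: [treatment]
  frailty1: true
  frailty2: true

dropout_model:
  family: loglogistic
  covariates: [disease_stage]

sampler:
  chains: 4
  draws: 1000
  warmup: 1000

diagnostics:
  replicates: 100
  k_max: 8

effects:
  direction: 1
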