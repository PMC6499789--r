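n_species: 20
n_mediators: 15
q_p: 0.2
q_c: 0.2
fac_fraction: 0.5
depletable_fraction: 1.0
rho_max: 0.2
strength_distribution: uniform
alpha_mean: 1.0
beta_mean: 0.1
K_sat: 10000.0
r0_low: 0.08
r0_high: 0.12
seed: 1.0
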