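# Example scheme configuration: small population, moderate dam selection,
# many sires, the 200-locus trait with moderate negative maternal-direct
# covariance.  All keys are optional; omitted ones take package defaults.
n_queens: 200
kd: 3
ks: 10
years: 100
n_loci: 200
sigma_a: [1.0, 2.0, -0.75]
sigma_e2: 1.0
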