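# Balanced four-group design: equal group sizes, leading block of four DIF
# items with slope offsets +/-0.5 and intercept offsets +/-1.0, impact means
# spread over [-0.5, 0.5] with common unit variance.
S: 4
group_sizes: [500, 500, 500, 500]
J: 20
n_dif_items: 4
dif_a: 0.5
dif_b: 1.0
base_a_dist: {name: lognormal, meanlog: 0.0, sdlog: 0.25}
base_b_dist: {name: normal, mean: 0.0, sd: 1.0}
impact_means: [0.0, -0.5, 0.0, 0.5]
impact_var: 1.0
missing_rate: 0.0
seed: 1
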