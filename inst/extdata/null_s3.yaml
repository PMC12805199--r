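# DIF-free three-group calibration design: impact only (means 0, -0.3, 0.3),
# no item shows DIF, used to measure false positive rates.
S: 3
group_sizes: [500, 500, 500]
J: 15
n_dif_items: 0
dif_a: 0.0
dif_b: 0.0
base_a_dist: {name: lognormal, meanlog: 0.0, sdlog: 0.25}
base_b_dist: {name: normal, mean: 0.0, sd: 1.0}
impact_means: [0.0, -0.3, 0.3]
impact_var: 1.0
missing_rate: 0.0
seed: 1
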