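# Unbalanced four-group design: group shares follow a geometric decay
# (ratio 0.6) of the total sample, otherwise identical to balanced_s4.
S: 4
group_sizes: [920, 550, 330, 200]
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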