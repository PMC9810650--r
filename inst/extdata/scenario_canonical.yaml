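# Canonical two-group simulation scenario: hypothetical cytokine expression
# in two sample groups with additive, gamma-scaled assay noise.
n_per_group: 12
seed: 1
signal_x: {family: normal, location: 10, scale: 2}
signal_y: {family: normal, location: 12.5, scale: 2}
noise_x: {family: normal, location: 0, scale: 1}
noise_y: {family: normal, location: 0, scale: 1}
gamma: {min: 0.25, max: 8, count: 32, spacing: linear}
r_replicates: [1, 3]
k_smooth: 1
test: welch_t
alpha: 0.05
n_analytes: 6
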