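# No group difference: null-calibration fixture
n_p = 10
n_t = 120
tr_seconds = 2
n_per_group = 10
base_density = 0.1
n_diff_edges = 0
effect = 0
subject_noise = 0.05
seed = 1
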