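# Weak planted group difference
n_p = 20
n_t = 180
tr_seconds = 2
n_per_group = 19
base_density = 0.1
n_diff_edges = 5
effect = 0.15
subject_noise = 0.05
seed = 1
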