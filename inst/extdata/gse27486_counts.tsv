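quantity	value
n_human_mirnas_quantified	1282
n_mirnas_expressed	395
n_human_probes	1305
n_empty_spots_per_array	548
n_cases	22
n_controls	23
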