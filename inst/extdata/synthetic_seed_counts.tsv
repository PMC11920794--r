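line	n_green	n_red	n_total
wild_type	182	175	1800
mutant_a	121	117	1800
mutant_b	139	128	1800
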