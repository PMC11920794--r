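chrA	999999	1400000
chrB	299999	700000
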