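chrom	length	centromere_mid
chrA	2e+06	1200000
chrB	1500000	5e+05
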