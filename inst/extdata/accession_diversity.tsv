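accession	pi_nonsyn	pi_syn
Y17	0.001417	0.001142
Y21	0.002784	0.003121
Y7	0.008596	0.009470
PaEU_invasive	0.004491	0.007634
CN	0.004636	0.013686
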