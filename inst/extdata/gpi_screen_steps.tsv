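alleles	covered
22	11
40	15
71	18
115	20
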