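clone	responsible_genes	total_mutations
B3-1	Pigt	220
B5-1	Dpm1	297
B7-2	Pigo	218
B102	Pigb	10
B201	Pigk	41
B502	Dpm1,Pigv	511
B1001	Pigv	306
B1002	Pigs	330
B1007	Gpaa1	23
F-43	Pigo	375
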