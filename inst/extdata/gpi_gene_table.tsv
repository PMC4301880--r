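gene	chromosome	cds_length_bp	alleles
Pigc	1	891	4
Pigm	1	1269	9
Pign	1	2793	NA
Dpm1	2	780	5
Dpm2	2	252	1
Pigt	2	1746	8
Pigu	2	1305	13
Dpm3	3	276	1
Pigk	3	1185	8
Pigo	4	3303	9
Pigv	4	1479	11
Pigg	5	2925	NA
Pgap2	7	750	4
Pigb	9	1626	10
Pigy	9	213	0
Mpdu1	11	741	0
Pigl	11	756	4
Pigs	11	1665	3
Pigw	11	1509	2
Pigh	12	564	1
Gpaa1	15	1863	7
Pigp	16	396	2
Pigx	16	756	9
Pigf	17	657	4
Pigq	17	1743	NA
Piga	X	1455	NA
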