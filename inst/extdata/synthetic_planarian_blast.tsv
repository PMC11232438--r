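dd_Smed_v6_105_0_1	SMED_SOXP3	95.0	100	5	0	1	100	1	100	1e-40	400.0
dd_Smed_v6_101_0_2	SMED_PITX	89.9	100	10	0	1	100	1	100	1e-40	400.0
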