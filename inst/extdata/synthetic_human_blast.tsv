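dd_Smed_v6_102_0_1	HS_GATA4	55.0	100	45	0	1	100	1	100	1e-20	200.0
dd_Smed_v6_103_0_1	HS_RPL11	80.0	100	20	0	1	100	1	100	1e-30	300.0
dd_Smed_v6_103_0_1	HS_FOXA2	45.0	100	55	0	1	100	1	100	1e-8	90.0
dd_Smed_v6_104_0_1	HS_PAX6	60.0	100	40	0	1	100	1	100	1e-4	50.0
dd_Smed_v6_104_0_1	HS_HIST1	70.0	100	30	0	1	100	1	100	1e-12	150.0
dd_Smed_v6_106_0_1	HS_ASCL1	62.0	100	38	0	1	100	1	100	1e-18	180.0
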