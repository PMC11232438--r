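transcript	length
dd_Smed_v6_101_0_1	900
dd_Smed_v6_101_0_2	1200
dd_Smed_v6_102_0_1	700
dd_Smed_v6_103_0_1	800
dd_Smed_v6_104_0_1	600
dd_Smed_v6_105_0_1	500
dd_Smed_v6_106_0_1	1100
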