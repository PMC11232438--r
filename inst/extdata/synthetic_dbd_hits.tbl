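#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----
# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target
#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- --- --- --- --- --- --- --- --- ---------------------
dd_Smed_v6_101_0_1 - Homeodomain PF00046.1 1e-30 95.2 0.1 2e-30 94.0 0.1 1.1 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_101_0_2 - Homeodomain PF00046.1 1e-25 88.0 0.1 2e-25 87.1 0.1 1.1 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_102_0_1 - zf-C2H2 PF00096.1 1e-12 60.3 0.0 2e-12 59.5 0.0 1.0 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_103_0_1 - Forkhead PF00250.1 1e-15 70.8 0.0 2e-15 69.9 0.0 1.0 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_104_0_1 - Homeodomain PF00046.1 1e-9 45.1 0.2 2e-9 44.3 0.2 1.2 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_105_0_1 - zf-C2H2 PF00096.1 1e-8 40.9 0.1 2e-8 40.0 0.1 1.0 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_106_0_1 - HLH PF00010.1 1e-20 80.5 0.0 2e-20 79.6 0.0 1.0 1 0 0 1 1 1 1 synthetic translated contig
dd_Smed_v6_106_0_1 - Homeodomain PF00046.1 1e-6 30.2 0.0 2e-6 29.5 0.0 1.0 1 0 0 1 1 1 1 synthetic translated contig
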