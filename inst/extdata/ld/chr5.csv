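RS_number,rs2075786,rs10054203,rs7726159,rs7705526,rs2736100,rs2853677,rs2736108,rs401681,rs2966952,rs3733890
rs2075786,1,0.02,0.047,0.023,0.003,0,0.014,0.016,0,0.002
rs10054203,0.02,1,0.607,0.454,0.316,0.061,0.001,0.013,0.001,0
rs7726159,0.047,0.607,1,0.788,0.516,0.181,0.015,0.003,0,0
rs7705526,0.023,0.454,0.788,1,0.51,0.185,0.042,0,0.001,0.001
rs2736100,0.003,0.316,0.516,0.51,1,0.435,0.149,0.004,0,0.001
rs2853677,0,0.061,0.181,0.185,0.435,1,0.22,0.014,0,0.001
rs2736108,0.014,0.001,0.015,0.042,0.149,0.22,1,0.174,0.001,0.001
rs401681,0.016,0.013,0.003,0,0.004,0.014,0.174,1,0.001,0
rs2966952,0,0.001,0,0.001,0,0,0.001,0.001,1,0
rs3733890,0.002,0,0,0.001,0.001,0.001,0.001,0,0,1
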