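RS_number,rs6772228,rs55749605,rs12638862,rs12696304,rs2293607,rs10936599,rs1317082,rs3772190,rs10936600,rs16847897,rs1920116
rs6772228,1,0,0,0,0,0,0,0,0,0,0
rs55749605,0,1,0.001,0.002,0.001,0,0,0,0,0.001,0.001
rs12638862,0,0.001,1,0.945,0.933,0.928,0.928,0.928,0.928,0.479,0.479
rs12696304,0,0.002,0.945,1,0.881,0.876,0.876,0.876,0.876,0.458,0.452
rs2293607,0,0.001,0.933,0.881,1,0.995,0.995,0.995,0.995,0.524,0.524
rs10936599,0,0,0.928,0.876,0.995,1,1,1,1,0.528,0.528
rs1317082,0,0,0.928,0.876,0.995,1,1,1,1,0.528,0.528
rs3772190,0,0,0.928,0.876,0.995,1,1,1,1,0.528,0.528
rs10936600,0,0,0.928,0.876,0.995,1,1,1,1,0.528,0.528
rs16847897,0,0.001,0.479,0.458,0.524,0.528,0.528,0.528,0.528,1,0.99
rs1920116,0,0.001,0.479,0.452,0.524,0.528,0.528,0.528,0.528,0.99,1
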