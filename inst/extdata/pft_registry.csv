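pft,pathway,gm_max25,gm_max25_ci260,Vcmax25_Ci,Jmax25_Ci,Vpmax25_Ci,g1
DNF,C3,0.057,0.054,33.1,62.9,NA,2.35
TDF,C3,0.058,0.056,31.0,58.9,NA,4.45
ENF,C3,0.078,0.074,52.7,100.1,NA,2.35
DSH,C3,0.098,0.100,49.8,94.7,NA,4.70
EBF,C3,0.101,0.100,61.4,116.7,NA,4.12
TRF,C3,0.152,0.151,39.0,74.1,NA,3.77
DBF,C3,0.175,0.172,52.1,98.9,NA,4.45
C3G,C3,0.197,0.198,50.1,95.2,NA,5.25
RSH,C3,0.224,0.230,49.8,94.7,NA,4.70
C3C,C3,0.295,0.305,80.2,152.4,NA,5.79
C4G,C4,0.55,0.55,27.5,NA,55,1.62
C4C,C4,0.739,0.739,30,NA,60,1.62
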