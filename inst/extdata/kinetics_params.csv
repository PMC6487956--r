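set,Kc25,Ko25,GammaStar25,Ea_Kc,Ea_Ko,Ea_GammaStar,Ha,Hd,dS
rubisco_Ci,404.9,278.4,42.75,79430,36380,37830,NA,NA,NA
rubisco_Cc,272.38,165.82,37.43,80990,23720,24460,NA,NA,NA
gm_temperature,NA,NA,NA,NA,NA,NA,49600,437400,1400
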