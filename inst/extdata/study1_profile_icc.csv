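measure,RTLS_Total,RTLS_Emotional,RTLS_Social,UCLA_20,UCLA_3,SI_Direct,SI_Indirect,SI_DirectFreq
RTLS_Total,NA,NA,NA,NA,NA,NA,NA,NA
RTLS_Emotional,0.98,NA,NA,NA,NA,NA,NA,NA
RTLS_Social,0.97,0.93,NA,NA,NA,NA,NA,NA
UCLA_20,0.98,0.94,0.97,NA,NA,NA,NA,NA
UCLA_3,0.96,0.98,0.92,0.93,NA,NA,NA,NA
SI_Direct,0.88,0.94,0.84,0.82,0.93,NA,NA,NA
SI_Indirect,0.89,0.94,0.87,0.84,0.92,0.99,NA,NA
SI_DirectFreq,0.87,0.94,0.82,0.8,0.93,0.99,0.98,NA
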