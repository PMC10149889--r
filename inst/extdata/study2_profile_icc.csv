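measure,RTLS_Total,RTLS_Emotional,RTLS_Social,UCLA_8,UCLA_3,SI_Direct
RTLS_Total,NA,NA,NA,NA,NA,NA
RTLS_Emotional,0.97,NA,NA,NA,NA,NA
RTLS_Social,0.88,0.77,NA,NA,NA,NA
UCLA_8,0.96,0.91,0.9,NA,NA,NA
UCLA_3,0.95,0.98,0.79,0.93,NA,NA
SI_Direct,0.98,0.98,0.84,0.95,0.99,NA
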