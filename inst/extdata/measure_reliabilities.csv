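study,measure,rel_self,rel_informant
study1,RTLS_Total,0.89,0.87
study1,RTLS_Emotional,0.8,0.83
study1,RTLS_Social,0.87,0.82
study1,UCLA_20,0.94,0.93
study1,UCLA_3,0.78,0.8
study1,SI_Direct,0.71,NA
study1,SI_Indirect,0.82,NA
study1,SI_DirectFreq,0.77,NA
study2,RTLS_Total,0.78,0.79
study2,RTLS_Emotional,0.68,0.66
study2,RTLS_Social,0.83,0.85
study2,UCLA_8,0.8,0.81
study2,UCLA_3,0.77,0.81
study2,SI_Direct,0.71,NA
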