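measure,inf_RTLS_Total,inf_RTLS_Emotional,inf_RTLS_Social,inf_UCLA_20,inf_UCLA_3,inf_SI_Direct,inf_SI_Indirect,inf_SI_DirectFreq
self_RTLS_Total,0.61,NA,NA,NA,NA,NA,NA,NA
self_RTLS_Emotional,0.56,0.57,NA,NA,NA,NA,NA,NA
self_RTLS_Social,0.58,0.56,0.52,NA,NA,NA,NA,NA
self_UCLA_20,0.59,0.57,0.51,0.61,NA,NA,NA,NA
self_UCLA_3,0.48,0.47,0.41,0.44,0.57,NA,NA,NA
self_SI_Direct,0.46,0.47,0.36,0.39,0.43,0.49,NA,NA
self_SI_Indirect,0.51,0.52,0.39,0.42,0.5,0.51,0.55,NA
self_SI_DirectFreq,0.43,0.44,0.34,0.41,0.39,0.48,0.51,0.53
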