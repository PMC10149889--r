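measure,inf_RTLS_Total,inf_RTLS_Emotional,inf_RTLS_Social,inf_UCLA_8,inf_UCLA_3,inf_SI_Direct
self_RTLS_Total,0.53,NA,NA,NA,NA,NA
self_RTLS_Emotional,0.47,0.49,NA,NA,NA,NA
self_RTLS_Social,0.43,0.32,0.42,NA,NA,NA
self_UCLA_8,0.48,0.42,0.41,0.55,NA,NA
self_UCLA_3,0.43,0.45,0.3,0.45,0.48,NA
self_SI_Direct,0.42,0.44,0.26,0.42,0.44,0.22
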