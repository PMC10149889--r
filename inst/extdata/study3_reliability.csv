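measure,rxx_full,lb_full,ub_full,rxx_panel,lb_panel,ub_panel
SI_Direct,0.71,0.65,0.76,0.74,0.66,0.77
SI_Indirect,0.82,0.77,0.85,0.85,0.81,0.88
SI_DirectFreq,0.77,0.71,0.81,0.8,0.74,0.84
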