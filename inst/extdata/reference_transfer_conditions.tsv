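train	test	ca_nontarget	ca_nontarget_sd	ca_target	ca_target_sd	ca_total	ca_total_sd
SF	SF	0.822	0.059	0.803	0.056	0.812	0.057
CF	SF	0.817	0.060	0.412	0.107	0.619	0.060
SF	CF	0.753	0.058	0.551	0.099	0.652	0.066
CF	CF	0.878	0.060	0.848	0.056	0.863	0.057
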