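breed	n_cnvs	n_gains	n_losses
Mongolia	82	42	40
Abaga	112	54	58
Hequ	211	91	120
Kazakh	157	54	103
Debao	138	61	77
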