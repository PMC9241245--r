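population	prevalence
European	0.100
African	0.125
Hispanic	0.131
Asian	0.137
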