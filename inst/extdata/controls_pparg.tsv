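name	binding_energy	contacts
GW9662	-7.98	Ser289;Cys285
G3335	-5.64	Tyr473;Met364;His323;Ser289
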