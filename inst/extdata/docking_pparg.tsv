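ligand	hpepdock_score	binding_energy	contacts
ITY	-126.941	-5.91	Met364;His323;Cys285
TSF	-123.304	-4.68	Cys285;Ser289
PEW	-157.801	-6.38	Ser342
PSQK	-152.549	-7.04	Ser342;Ile262;Glu291
TTPW	-145.896	-5.96	Cys285;Gly284
ATSF	-137.604	-3.89	Cys285;Ser342
VSVGF	-157.768	-5.97	Glu291
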