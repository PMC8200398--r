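sample_id	protein_pct	fat_pct	fiber_pct	carb_pct
RF	23.46	1.89	2.96	66.02
CF	25.27	1.09	2.44	68.35
RPC	71.38	5.12	NA	15.59
CPC	62.69	9.97	NA	18.34
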