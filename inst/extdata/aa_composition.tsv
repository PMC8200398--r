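item	RF	CF	RPC	CPC
Asp	7.64	7.50	6.83	6.50
Glu	13.54	11.05	13.71	15.13
Ser	1.42	1.86	1.46	0.90
His	5.51	5.02	6.23	8.49
Gly	3.67	3.16	4.31	4.23
Thr	7.56	8.46	12.13	10.61
Arg	5.45	4.04	4.96	3.69
Ala	2.50	2.80	3.95	3.10
Meth+Cys	1.65	1.99	1.89	1.65
Val	8.90	6.13	6.31	7.30
Phe+Tyr	11.99	10.63	8.77	11.97
Ile	4.18	3.97	4.59	4.75
Leu	6.25	6.47	7.31	7.92
Thr	7.56	8.46	12.13	10.61
Trp	1.10	1.20	0.90	1.20
Lys	3.48	4.34	1.89	4.86
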