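sample_id	ivpd_pct
RF	48.20
CF	61.77
RPC	49.80
CPC	63.61
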