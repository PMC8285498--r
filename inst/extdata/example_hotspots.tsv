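gene	protein_position
ESR1	537
ESR1	538
PIK3CA	545
PIK3CA	1047
TP53	175
TP53	248
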