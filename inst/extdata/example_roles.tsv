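gene	role
ESR1	oncogene
TP53	both
CDH1	tsg
PIK3CA	oncogene
RICTOR	oncogene
ARID2	tsg
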