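Hugo_Symbol	S001	S002	S003
ERBB2	2	0	0
PTEN	0	-2	-1
ESR1	0	0	2
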