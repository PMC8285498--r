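sample_id	gene	level
S001	ERBB2	2
S001	PTEN	-2
S002	ESR1	1
S002	RB1	-1
S003	CCND1	-1.5
S003	MYC	0
S004	FGFR1	AMP
S004	CDKN2A	HOM_DEL
S005	EGFR	3
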