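Hugo_Symbol	Chromosome	Start_Position	End_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification	HGVSp_Short	t_depth	t_alt_count	Tumor_Sample_Barcode
ESR1	chr6	152419920	152419920	A	G	Missense_Mutation	p.D538G	210	63	S001
ESR1	6	152419923	152419923	T	C	Missense_Mutation	p.Y537S	180	36	S002
TP53	17	7577120	7577120	C	T	Nonsense_Mutation	p.R306*	95	28	S002
MLL	11	118307205	118307205	G	A	Missense_Mutation	p.A100T	150	45	S003
MLL2	12	49426000	49426000	C	G	Silent	p.L500L	120	24	S003
CDH1	16	68842000	68842001	AG	-	Frame_Shift_Del	p.Q23fs	88	22	S004
PIK3CA	3	178936091	178936091	G	A	Missense_Mutation	p.E545K	8	3	S004
ESR1	6	152419920	152419920	A	G	Missense_Mutation	p.D538G	210	1	S005
ESR1	6	abc	152419920	A	G	Missense_Mutation	p.D538G	100	30	S006
TP53	17	7577500	7577500			Missense_Mutation	p.R175H	100	30	S006
BRCA2	13	32914000	32914000	G	T	WeirdClass	p.E100*	100	30	S006
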