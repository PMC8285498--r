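variant_key	tool	impact	tsg_evidence
ESR1 p.D538G	mutation_assessor	high
ESR1 p.D538G	polyphen2	high
ESR1 p.D538G	sift	high
ESR1 p.Y537S	mutation_assessor	high
ESR1 p.Y537S	polyphen2	medium
ESR1 p.Y537S	sift	low
CDH1 Trunc			strong
TP53 Trunc			weak
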