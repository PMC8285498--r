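old_symbol	hgnc_symbol
MLL	KMT2A
MLL2	KMT2D
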