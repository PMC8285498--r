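panel_id	gene	full_exonic
PANEL_A	ESR1	TRUE
PANEL_A	TP53	TRUE
PANEL_A	KMT2A	TRUE
PANEL_A	KMT2D	TRUE
PANEL_A	CDH1	TRUE
PANEL_A	PIK3CA	TRUE
PANEL_B	ESR1	FALSE
PANEL_B	TP53	FALSE
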