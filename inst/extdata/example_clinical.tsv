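sample_id	patient_id	tumor_type	biopsy_site	sex	histology	hr_status	her2_status	treatment_status	age	panel_id
S001	P001	Metastasis	Liver	Female	Breast Invasive Ductal Carcinoma	Positive	Negative	post_treatment_metastasis	54	PANEL_A
S002	P002	Metastasis	Regional lymph nodes	Female	Breast Invasive Lobular Carcinoma	Positive	Negative		61	PANEL_A
S003	P003	Metastasis	Bone	Female	Breast Invasive Ductal Carcinoma		Positive		48	PANEL_A
S004	P004	Primary	Breast	Female	Breast Invasive Ductal Carcinoma	Negative	Negative	naive_primary	57	PANEL_A
S005	P005	Primary	Breast	Female	Other histology	Positive	Negative	naive_primary	63	PANEL_B
S006	P006	Metastasis	Brain	Male	Breast Invasive Ductal Carcinoma	Negative	Negative		52	PANEL_A
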