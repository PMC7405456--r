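entity	n_cases	alteration	n_altered
astrocytic_glioma_IDHmut	19	IDH1/2	19
astrocytic_glioma_IDHmut	19	TP53	18
astrocytic_glioma_IDHmut	19	ATRX	7
astrocytic_glioma_IDHmut	19	CDKN2A_HomDel	2
oligodendroglioma_IDHmut_codel	14	IDH1/2	14
oligodendroglioma_IDHmut_codel	14	1p/19q_LOH	14
oligodendroglioma_IDHmut_codel	14	TERTp	14
oligodendroglioma_IDHmut_codel	14	CIC	11
oligodendroglioma_IDHmut_codel	14	FUBP1	4
astrocytic_glioma_IDHwt	42	TERTp	30
astrocytic_glioma_IDHwt	42	10DEL_7AMP	14
astrocytic_glioma_IDHwt	42	EGFR_Highcopy	9
astrocytic_glioma_IDHwt	42	TP53	9
astrocytic_glioma_IDHwt	42	NF1	5
astrocytic_glioma_IDHwt	42	BRAF	4
diffuse_midline_glioma_H3K27M	2	H3F3A	2
diffuse_midline_glioma_H3K27M	2	TP53	2
meningioma	19	NF2	15
meningioma	19	SMARCB1	15
meningioma	19	1p_DEL	12
meningioma	19	CDKN2A_HomDel	4
meningioma	19	TERTp	0
medulloblastoma	8	TERTp	3
medulloblastoma	8	TP53	2
medulloblastoma	8	OTX2_Highcopy	1
medulloblastoma	8	CTNNB1	1
medulloblastoma	8	Monosomy_6	1
medulloblastoma	8	Isochromosome_17	1
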