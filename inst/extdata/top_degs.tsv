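# Top 10 differentially expressed genes per lactation-stage comparison:
# FDR q-value and log2 fold change (b vs a). "inf" marks a gene expressed
# in only the second condition.
comparison	gene	description	q_value	log2fc
EARLY_VS_DRY	LRRC73	leucine rich repeat containing 73	0.004690	inf
EARLY_VS_DRY	GPX3	glutathione peroxidase 3	0.004690	5.57
EARLY_VS_DRY	APOA4	apolipoprotein A4	0.004690	4.26
EARLY_VS_DRY	HP	haptoglobin	0.004690	4.07
EARLY_VS_DRY	MFSD2	major facilitator superfamily domain containing 2A	0.004690	3.67
EARLY_VS_DRY	CDC42EP5	CDC42 effector protein 5	0.004690	3.46
EARLY_VS_DRY	SLC13A5	solute carrier family 13	0.011199	3.22
EARLY_VS_DRY	SMCT1	solute carrier family 5	0.004690	3.22
EARLY_VS_DRY	PAQR9	progestin and adipoQ receptor family member IX	0.004690	3.14
EARLY_VS_DRY	SFRP2	secreted frizzled-related protein 2	0.008110	-3.62
PEAK_VS_DRY	ISG15	ISG15 ubiquitin like modifier	0.004690	5.09
PEAK_VS_DRY	IFIT1	interferon-induced protein with tetratricopeptide repeats 1	0.004690	4.98
PEAK_VS_DRY	RSAD2	radical S-adenosyl methionine domain containing 2	0.004690	4.24
PEAK_VS_DRY	APOA4	apolipoprotein A4	0.004690	3.64
PEAK_VS_DRY	MX1	MX dynamin like GTPase 1	0.004690	3.61
PEAK_VS_DRY	GPX3	glutathione peroxidase 3	0.004690	3.54
PEAK_VS_DRY	MX2	MX dynamin like GTPase 2	0.004690	3.42
PEAK_VS_DRY	USP18	ubiquitin specific peptidase 18	0.004690	3.39
PEAK_VS_DRY	LOC100298356	bone marrow stromal antigen 2	0.004690	3.33
PEAK_VS_DRY	HERC6	HECT and RLD domain containing E3 ubiquitin protein ligase family member 6	0.004690	3.15
PEAK_VS_EARLY	ISG12(B)	TLH29 protein precursor-like	0.004690	4.26
PEAK_VS_EARLY	RSAD2	radical S-adenosyl methionine domain containing 2	0.004690	4.13
PEAK_VS_EARLY	IFIT1	interferon-induced protein with tetratricopeptide repeats 1	0.004690	4.12
PEAK_VS_EARLY	ISG15	ISG15 ubiquitin like modifier	0.004690	3.17
PEAK_VS_EARLY	FKBP5	FKBP prolyl isomerase 5	0.004690	2.48
PEAK_VS_EARLY	MX1	MX dynamin-like GTPase 1	0.017022	2.42
PEAK_VS_EARLY	RXRG	retinoid X receptor, gamma	0.004690	-2.42
PEAK_VS_EARLY	ITGAD	intrgrin, alpha D	0.004690	-2.48
PEAK_VS_EARLY	LYZ2	lysozyme C-2	0.011199	-2.81
PEAK_VS_EARLY	HBB	hemoglobin, beta	0.004690	-5.54
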