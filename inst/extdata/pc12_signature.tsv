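#reosig_signature	v1
#k	12
#provenance	Published 12-gene-pair / 17-gene panel for pancreatic cancer diagnosis; gene_a is oriented above gene_b in tumor samples. Recorded assumption: gene A of the published table is the tumor-high member, consistent with the documented tumor overexpression of LAMC2, S100P, CST6 and CDH3.
gene_a	gene_b	score
LAMC2	TEX11	NA
LAMC2	HDAC11	NA
PITX1	KCNH6	NA
S100P	AP1M1	NA
LAMC2	FOXRED2	NA
S100P	AIP	NA
LAMC2	MYOM2	NA
CST6	VIPR2	NA
CDH3	EXOSC5	NA
S100P	MAP1LC3B	NA
CST6	KIRREL2	NA
CDH3	TP53RK	NA
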