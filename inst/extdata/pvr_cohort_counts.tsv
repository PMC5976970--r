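# Case-control genotype counts for four inflammation-gene SNPs in a
# proliferative vitreoretinopathy (PVR) cohort: 96 healthy controls vs
# PVR patients (113 genotyped for rs17561/rs2069763, 153 for
# rs2229094/rs1800629). n_missing counts enrolled individuals whose
# genotype could not be determined.
population	snp_id	gene	allele_major	allele_minor	n_hom_major	n_het	n_hom_minor	n_missing
control	rs17561	IL1A	C	A	49	38	9	0
case	rs17561	IL1A	C	A	49	59	3	2
control	rs2069763	IL2	C	A	39	39	18	0
case	rs2069763	IL2	C	A	52	46	15	0
control	rs2229094	LTA	T	C	55	33	8	0
case	rs2229094	LTA	T	C	79	55	15	4
control	rs1800629	TNF	G	A	74	20	2	0
case	rs1800629	TNF	G	A	96	54	3	0
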