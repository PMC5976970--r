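# MAF-perturbation demonstration pair. The case dataset (AA=1, AG=39,
# GG=73) is the published simulation input. The control dataset is a
# SYNTHETIC RECONSTRUCTION (the original was never published): n=96
# counts chosen by grid search so that the baseline genotypic Pearson
# chi-square P value is ~0.13 and the heterozygote-only addition series
# crosses alpha=0.05 between 5 and 6 added individuals.
population	snp_id	gene	allele_major	allele_minor	n_hom_major	n_het	n_hom_minor	n_missing
case	snp_sim	NA	G	A	73	39	1	0
control	snp_sim	NA	G	A	74	21	1	0
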