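gene_id	chrom	n_informative_snps	expressed_parent	fetal_brain_percent	placenta_percent
Ipncr1	chr1	3	Maternal	95.5	NA
Pou5f3	chr1	2	Paternal	97.8	71.6
Npdc1	chr1	7	Paternal	97.7	90.0
Rwdd2a	chr2	3	Paternal	99.4	98.6
Zfp68	chr2	1	Paternal	100.0	100.0
Ipncr5	chr3	3	Paternal	98.1	97.6
Ipncr2	chr6	4	Paternal	98.6	NA
Nkrfl1	chr6	3	Paternal	99.9	100.0
Nkrfl2	chr6	3	Paternal	99.9	99.7
Fam169a	chr3	2	Maternal	98.6	94.2
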