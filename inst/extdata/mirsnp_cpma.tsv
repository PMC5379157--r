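# published cross-phenotype (CPMA) p-values per SNP, with published BH-adjusted values where available
rsid	p	p_fdr_printed
rs2292832	0.2965	NA
rs2910164	0.00111	0.00922
rs2043556	0.0165	0.0495
rs4919510	0.069	NA
rs1834306	0.2303	NA
rs11614913	0.1233	NA
rs6505162	0.00205	0.00922
rs895819	0.0284	0.0639
rs3746444	0.1296	NA
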