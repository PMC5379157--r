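# published per-cancer association summaries: nine microRNA-gene SNPs x eight cancer case-control studies
# columns: OR and 95% CI per effect-allele copy (additive model), two-sided p; p_fdr_printed = published BH value where available
rsid	chr	mirna	effect_allele	genotyped	study	cancer_type	n_cases	n_controls	or_	ci_low	ci_high	p	p_fdr_printed
rs2292832	2	miR149	T	TRUE	bladder	Bladder cancer	3527	5119	1.02	0.95	1.09	0.5868	NA
rs2292832	2	miR149	T	TRUE	breast	Breast cancer	1145	1142	0.91	0.8	1.03	0.1418	NA
rs2292832	2	miR149	T	TRUE	escc	ESCC	1898	2100	1.02	0.93	1.13	0.6097	NA
rs2292832	2	miR149	T	TRUE	gastric	Gastric cancer	1625	2100	1.02	0.92	1.12	0.7599	NA
rs2292832	2	miR149	T	TRUE	lung	Lung cancer	3782	3840	0.98	0.91	1.05	0.4977	NA
rs2292832	2	miR149	T	TRUE	pancreatic	Pancreatic cancer	2452	2461	1.03	0.95	1.13	0.4548	NA
rs2292832	2	miR149	T	TRUE	prostate	Prostate cancer	659	1593	0.99	0.86	1.14	0.8873	NA
rs2292832	2	miR149	T	TRUE	rcc	RCC	1311	3424	1.03	0.93	1.14	0.5841	NA
rs2910164	5	miR146a	C	FALSE	bladder	Bladder cancer	3527	5119	1.12	1.04	1.21	0.00206	0.0297
rs2910164	5	miR146a	C	FALSE	breast	Breast cancer	1145	1142	0.91	0.79	1.04	0.1667	NA
rs2910164	5	miR146a	C	FALSE	escc	ESCC	1898	2100	0.94	0.86	1.03	0.2022	NA
rs2910164	5	miR146a	C	FALSE	gastric	Gastric cancer	1625	2100	0.85	0.77	0.93	0.000598	0.0108
rs2910164	5	miR146a	C	FALSE	lung	Lung cancer	3782	3840	1.08	1	1.17	0.0623	NA
rs2910164	5	miR146a	C	FALSE	pancreatic	Pancreatic cancer	2452	2461	1.03	0.94	1.13	0.5733	NA
rs2910164	5	miR146a	C	FALSE	prostate	Prostate cancer	659	1593	1.04	0.89	1.22	0.5841	NA
rs2910164	5	miR146a	C	FALSE	rcc	RCC	1311	3424	1.01	0.9	1.13	0.8238	NA
rs2043556	10	miR605	C	TRUE	bladder	Bladder cancer	3527	5119	1.19	1.1	1.28	1.44e-05	0.000518
rs2043556	10	miR605	C	TRUE	breast	Breast cancer	1145	1142	1.05	0.91	1.2	0.5423	NA
rs2043556	10	miR605	C	TRUE	escc	ESCC	1898	2100	0.97	0.88	1.07	0.4995	NA
rs2043556	10	miR605	C	TRUE	gastric	Gastric cancer	1625	2100	0.98	0.89	1.09	0.7126	NA
rs2043556	10	miR605	C	TRUE	lung	Lung cancer	3782	3840	0.95	0.88	1.03	0.2572	NA
rs2043556	10	miR605	C	TRUE	pancreatic	Pancreatic cancer	2452	2461	0.95	0.86	1.04	0.2566	NA
rs2043556	10	miR605	C	TRUE	prostate	Prostate cancer	659	1593	0.96	0.82	1.12	0.5694	NA
rs2043556	10	miR605	C	TRUE	rcc	RCC	1311	3424	0.96	0.85	1.08	0.4774	NA
rs4919510	10	miR608	G	FALSE	bladder	Bladder cancer	3527	5119	1.11	1.02	1.21	0.0182	0.1971
rs4919510	10	miR608	G	FALSE	breast	Breast cancer	1145	1142	1	0.86	1.16	0.9956	NA
rs4919510	10	miR608	G	FALSE	escc	ESCC	1898	2100	0.97	0.89	1.07	0.5794	NA
rs4919510	10	miR608	G	FALSE	gastric	Gastric cancer	1625	2100	1.1	1	1.21	0.0418	0.2736
rs4919510	10	miR608	G	FALSE	lung	Lung cancer	3782	3840	1.04	0.95	1.14	0.3599	NA
rs4919510	10	miR608	G	FALSE	pancreatic	Pancreatic cancer	2452	2461	1	0.9	1.1	0.9397	NA
rs4919510	10	miR608	G	FALSE	prostate	Prostate cancer	659	1593	1.2	1.02	1.41	0.026	0.208
rs4919510	10	miR608	G	FALSE	rcc	RCC	1311	3424	0.91	0.81	1.04	0.1597	NA
rs1834306	11	miR100	A	FALSE	bladder	Bladder cancer	3527	5119	1.1	1.01	1.2	0.0213	0.1971
rs1834306	11	miR100	A	FALSE	breast	Breast cancer	1145	1142	1.02	0.89	1.15	0.8174	NA
rs1834306	11	miR100	A	FALSE	escc	ESCC	1898	2100	1.04	0.95	1.15	0.361	NA
rs1834306	11	miR100	A	FALSE	gastric	Gastric cancer	1625	2100	1.04	0.94	1.15	0.4405	NA
rs1834306	11	miR100	A	FALSE	lung	Lung cancer	3782	3840	1.06	0.98	1.14	0.1295	NA
rs1834306	11	miR100	A	FALSE	pancreatic	Pancreatic cancer	2452	2461	1	0.91	1.09	0.9386	NA
rs1834306	11	miR100	A	FALSE	prostate	Prostate cancer	659	1593	0.91	0.79	1.04	0.1609	NA
rs1834306	11	miR100	A	FALSE	rcc	RCC	1311	3424	1.09	0.98	1.21	0.1268	NA
rs11614913	12	miR196a2	T	TRUE	bladder	Bladder cancer	3527	5119	0.95	0.9	1.02	0.15	NA
rs11614913	12	miR196a2	T	TRUE	breast	Breast cancer	1145	1142	0.94	0.84	1.06	0.3188	NA
rs11614913	12	miR196a2	T	TRUE	escc	ESCC	1898	2100	0.94	0.86	1.03	0.1942	NA
rs11614913	12	miR196a2	T	TRUE	gastric	Gastric cancer	1625	2100	0.94	0.86	1.03	0.197	NA
rs11614913	12	miR196a2	T	TRUE	lung	Lung cancer	3782	3840	1.08	1.01	1.16	0.0219	0.1971
rs11614913	12	miR196a2	T	TRUE	pancreatic	Pancreatic cancer	2452	2461	1.04	0.96	1.13	0.3503	NA
rs11614913	12	miR196a2	T	TRUE	prostate	Prostate cancer	659	1593	0.91	0.79	1.05	0.1988	NA
rs11614913	12	miR196a2	T	TRUE	rcc	RCC	1311	3424	1.02	0.93	1.13	0.6741	NA
rs6505162	17	miR423	C	FALSE	bladder	Bladder cancer	3527	5119	1.12	1.06	1.18	4.05e-05	0.000972
rs6505162	17	miR423	C	FALSE	breast	Breast cancer	1145	1142	1.09	0.97	1.23	0.1494	NA
rs6505162	17	miR423	C	FALSE	escc	ESCC	1898	2100	0.97	0.87	1.09	0.5894	NA
rs6505162	17	miR423	C	FALSE	gastric	Gastric cancer	1625	2100	1.07	0.95	1.21	0.2689	NA
rs6505162	17	miR423	C	FALSE	lung	Lung cancer	3782	3840	1.05	0.98	1.13	0.148	NA
rs6505162	17	miR423	C	FALSE	pancreatic	Pancreatic cancer	2452	2461	1	0.92	1.09	0.9894	NA
rs6505162	17	miR423	C	FALSE	prostate	Prostate cancer	659	1593	0.94	0.82	1.07	0.3396	NA
rs6505162	17	miR423	C	FALSE	rcc	RCC	1311	3424	1.11	1.01	1.23	0.0376	0.6665
rs895819	19	miR27a	C	FALSE	bladder	Bladder cancer	3527	5119	1.19	1.1	1.28	6.7e-06	0.000482
rs895819	19	miR27a	C	FALSE	breast	Breast cancer	1145	1142	1.02	0.89	1.18	0.7482	NA
rs895819	19	miR27a	C	FALSE	escc	ESCC	1898	2100	1.05	0.93	1.18	0.456	NA
rs895819	19	miR27a	C	FALSE	gastric	Gastric cancer	1625	2100	1.05	0.92	1.18	0.4794	NA
rs895819	19	miR27a	C	FALSE	lung	Lung cancer	3782	3840	1.02	0.94	1.1	0.6004	NA
rs895819	19	miR27a	C	FALSE	pancreatic	Pancreatic cancer	2452	2461	1.04	0.95	1.14	0.4106	NA
rs895819	19	miR27a	C	FALSE	prostate	Prostate cancer	659	1593	0.95	0.81	1.11	0.5272	NA
rs895819	19	miR27a	C	FALSE	rcc	RCC	1311	3424	0.99	0.89	1.11	0.879	NA
rs3746444	20	miR499a/b	G	FALSE	bladder	Bladder cancer	3527	5119	1.09	0.99	1.2	0.0684	NA
rs3746444	20	miR499a/b	G	FALSE	breast	Breast cancer	1145	1142	0.9	0.77	1.04	0.1558	NA
rs3746444	20	miR499a/b	G	FALSE	escc	ESCC	1898	2100	0.96	0.81	1.13	0.6197	NA
rs3746444	20	miR499a/b	G	FALSE	gastric	Gastric cancer	1625	2100	1.05	0.88	1.24	0.6012	NA
rs3746444	20	miR499a/b	G	FALSE	lung	Lung cancer	3782	3840	0.93	0.85	1.01	0.0846	NA
rs3746444	20	miR499a/b	G	FALSE	pancreatic	Pancreatic cancer	2452	2461	0.93	0.84	1.03	0.1794	NA
rs3746444	20	miR499a/b	G	FALSE	prostate	Prostate cancer	659	1593	0.88	0.74	1.05	0.1575	NA
rs3746444	20	miR499a/b	G	FALSE	rcc	RCC	1311	3424	0.92	0.82	1.05	0.219	NA
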