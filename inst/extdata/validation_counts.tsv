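gene	rsid	cohort	hom_ref	het	hom_alt	printed_n	printed_af	printed_or	printed_ci_low	printed_ci_high	printed_p	note
PALB2	rs152451	CHEK2	64	6	0	70	0.043	0.623	0.256	1.518	0.293	
PALB2	rs152451	Familial	327	48	7	383	0.081	1.228	0.792	1.904	0.357	printed n 383 vs genotype sum 382
PALB2	rs152451	Sporadic	262	31	4	297	0.066	0.977	0.605	1.579	0.925	
PALB2	rs152451	Controls	216	27	3	246	0.067	NA	NA	NA	NA	
PRDM1	rs811925	CHEK2	44	26	1	71	0.197	1.087	0.679	1.739	0.728	
PRDM1	rs811925	Familial	243	129	18	390	0.211	1.187	0.895	1.574	0.232	
PRDM1	rs811925	Sporadic	200	103	12	315	0.201	1.117	0.831	1.503	0.463	
PRDM1	rs811925	Controls	170	76	9	255	0.184	NA	NA	NA	NA	
ADAM19	rs2287749	CHEK2	50	18	2	70	0.157	1.126	0.671	1.891	0.653	
ADAM19	rs2287749	Familial	256	103	7	366	0.160	1.149	0.837	1.578	1.149	p column prints the odds ratio (misprint); chi-square p is 0.389
ADAM19	rs2287749	Sporadic	230	71	3	304	0.127	0.876	0.621	1.236	0.451	
ADAM19	rs2287749	Controls	191	59	7	257	0.142	NA	NA	NA	NA	
CYP4B1	rs2297809	CHEK2	47	16	3	65	0.167	1.005	0.600	1.681	0.985	printed n 65 vs genotype sum 66
CYP4B1	rs2297809	Familial	255	81	14	350	0.156	0.927	0.678	1.266	0.632	
CYP4B1	rs2297809	Sporadic	227	45	17	289	0.137	0.795	0.569	1.111	0.179	
CYP4B1	rs2297809	Controls	177	63	10	250	0.166	NA	NA	NA	NA	
VWF	rs7962217	CHEK2	64	6	0	70	0.043	0.640	0.261	1.566	0.325	
VWF	rs7962217	Familial	340	38	3	381	0.058	0.876	0.545	1.408	0.583	
VWF	rs7962217	Sporadic	279	21	3	303	0.044	0.666	0.392	1.133	0.131	
VWF	rs7962217	Controls	209	25	3	237	0.065	NA	NA	NA	NA	
CASP10	rs17860405	CHEK2	60	8	1	69	0.072	1.078	0.520	2.236	0.840	
CASP10	rs17860405	Familial	342	25	0	367	0.034	0.487	0.288	0.823	0.006	
CASP10	rs17860405	Sporadic	270	19	0	289	0.033	0.469	0.265	0.831	0.008	
CASP10	rs17860405	Controls	228	27	4	259	0.067	NA	NA	NA	NA	
DLG1	rs34492126	CHEK2	63	8	0	71	0.056	1.155	0.505	2.642	0.732	
DLG1	rs34492126	Familial	344	41	2	387	0.058	1.194	0.713	2.001	0.499	
DLG1	rs34492126	Sporadic	266	34	0	300	0.057	1.162	0.675	2.001	0.587	
DLG1	rs34492126	Controls	213	19	2	234	0.049	NA	NA	NA	NA	
CDK5RAP2	rs34523498	CHEK2	65	5	0	71	0.036	1.125	0.405	3.126	0.791	printed n 71 vs genotype sum 70; printed p equals the Fisher exact p (0.7905), not the chi-square p (0.821) used elsewhere in the table
CDK5RAP2	rs34523498	Familial	358	24	0	382	0.031	0.985	0.518	1.874	0.963	
CDK5RAP2	rs34523498	Sporadic	285	22	1	309	0.039	1.231	0.647	2.344	0.526	printed n 309 vs genotype sum 308
CDK5RAP2	rs34523498	Controls	236	14	1	251	0.032	NA	NA	NA	NA	
TP53RK	rs34983477	CHEK2	60	10	0	70	0.071	1.133	0.538	2.386	0.743	
TP53RK	rs34983477	Familial	327	33	2	362	0.051	0.793	0.481	1.309	0.363	
TP53RK	rs34983477	Sporadic	255	30	2	287	0.059	0.927	0.556	1.546	0.927	p column prints the odds ratio (misprint); chi-square p is 0.772
TP53RK	rs34983477	Controls	204	19	5	228	0.063	NA	NA	NA	NA	
SIGIRR	rs117739035	CHEK2	65	5	0	70	0.0357	0.784	0.293	2.102	0.628	
SIGIRR	rs117739035	Familial	349	45	0	394	0.057	1.282	0.766	2.147	0.342	
SIGIRR	rs117739035	Sporadic	288	28	0	316	0.044	0.982	0.558	1.726	0.948	
SIGIRR	rs117739035	Controls	232	23	0	255	0.045	NA	NA	NA	NA	
NELL1	rs8176786	CHEK2	46	3	1	53	0.031	0.392	0.136	1.131	0.073	count run garbled in print; the printed OR/CI pin allele counts 4/102, irreconcilable with any digit reading, so this row is excluded from replication checks
NELL1	rs8176786	Familial	348	36	2	386	0.052	0.546	0.340	0.879	0.011	
NELL1	rs8176786	Sporadic	264	33	0	297	0.055	0.588	0.358	0.967	0.035	homozygote digit printed 2; 0 restored from the printed OR/CI (allele counts 33/561)
NELL1	rs8176786	Controls	158	24	5	187	0.091	NA	NA	NA	NA	
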