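chrom	start_bp	end_bp	cytoband	bp_nmce	bp_tumor	or_printed	bp_ccle	fragile_site
1	118000001	118100001	1p12	0	23	10.68	4	
2	4900001	5000001	2p25.2	0	23	10.68	26	FRA2M
4	88700001	88800001	4q22.1	0	24	11.26	2	FRA4F
5	45900001	46000001	5p12	0	24	11.26	1	
5	46300001	46400001	5p11	0	26	12.47	81	FRA5I
7	11700001	11800001	7p21.3	0	24	11.26	5	FRA7L
7	37600001	37700001	7p14.1	0	23	10.68	0	
7	103400001	103500001	7q22.1	1	23	4.97	1	FRA7F
8	43400001	43500001	8p11.1	0	25	11.86	2	FRA8I
8	43700001	43800001	8p11.1	0	32	16.46	48	FRA8I
8	47300001	47400001	8q11.1	0	23	10.68	1	FRA8I
9	141000001	141100001	9q34.3	1	48	14.48	321	FRA9N
13	35900001	36000001	13q13.3	0	23	10.68	1	
13	115100001	115106996	13q34	3	40	3.19	210	FRA13I
14	20400001	20500001	14q11.2	3	36	2.72	61	FRA14D
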