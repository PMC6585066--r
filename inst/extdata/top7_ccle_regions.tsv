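chrom	start_bp	end_bp	cytoband	bp_nmce	bp_tumor	or_printed	bp_ccle	fragile_site
2	20300001	20400001	2p24.1	0	9	3.73	248	
4	190900001	191000001	4q35.2	0	14	5.98	190	FRA4L,FRA4M
7	159100001	159119220	7q36.3	0	22	10.11	230	FRA7I
8	146200001	146300001	8q24.3	0	21	9.56	238	FRA8D
9	141000001	141100001	9q34.3	1	48	14.48	321	FRA9N
13	115100001	115106996	13q34	3	40	3.19	210	FRA13I
16	85000001	85100001	16q24.1	0	8	3.30	244	FRA16J
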