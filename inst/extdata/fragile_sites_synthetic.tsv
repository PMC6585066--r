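name	chrom	start_bp	end_bp
FRA2M	2	4850001	5050000
FRA4F	4	88650001	88850000
FRA4L	4	190850001	191050000
FRA4M	4	190900001	190950000
FRA5I	5	46250001	46450000
FRA7L	7	11650001	11850000
FRA7F	7	103350001	103550000
FRA7I	7	159050001	159119220
FRA8I	8	43400001	47400000
FRA8D	8	146150001	146350000
FRA9N	9	140950001	141150000
FRA13I	13	115050001	115106996
FRA14D	14	20350001	20550000
FRA16J	16	84950001	85150000
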