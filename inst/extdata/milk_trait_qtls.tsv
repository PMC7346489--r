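# Reported milk-production-trait QTLs near the screened genes: linkage
# confidence interval and peak position (cM). QTL 3536's peak lies outside
# its printed CI; the record is transcribed as given.
qtl_id	trait	chrom	ci_lo_cm	ci_hi_cm	peak_cm
2721	PY	18	54.713	76.57	66
1532	MY	18	54.713	76.57	65.6
10443	FY	19	14.1	60.4	43.1
2740	FP	27	15.176	52.32	33.8
1515	FY	2	115.437	130	120
2655	FY	3	22.61	27.41	25
2656	PP	3	22.61	27.41	25
3435	PP	3	6	32	27.41
3534	PP	7	16.75	39.33	17.8
3536	PP	7	16.75	39.33	15.9
2590	MY	23	11.82	20.66	15
2568	MY	23	13.77	28.30	15.1
2669	FY	11	92.17	97.57	94.9
2564	FY	20	0	31.86	8.238
2750	PY	20	0	20.165	10.08
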