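# Published gene-to-QTL-peak distances (cM, 1 decimal), one row per
# reported (gene, QTL) pair. known_discrepancy = 1 marks the LMNA rows
# whose printed distances do not equal |gene_cM - peak_cM| at 1 decimal
# under any stated convention; they are reported as EXPECTED_MISMATCH.
gene	qtl_id	printed_distance_cm	known_discrepancy
APOC2	2721	1.9	0
APOC2	1532	2.3	0
ACADVL	10443	4.0	0
PPP1R3B	2740	0.5	0
GALE	1515	1.9	0
PKLR	2655	0.7	0
PKLR	2656	0.7	0
PKLR	3435	1.7	0
ANGPTL4	3534	2.8	0
ANGPTL4	3536	4.7	0
CDKN1A	2590	0.9	0
CDKN1A	2568	1.0	0
ODC1	2669	0.1	0
LPIN1	2669	1.1	0
DUSP1	2564	2.7	0
DUSP1	2750	4.6	0
LMNA	2655	0.5	1
LMNA	2656	0.5	1
LMNA	3435	2.9	1
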