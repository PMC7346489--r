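# Bovine milk-trait candidate screen: gene features (UMD3.1.80 coordinates,
# 1-based inclusive). linkage_cm is the published linkage position where
# reported; NA where only the physical position is known.
gene	chrom	start_bp	end_bp	linkage_cm
APOC2	18	53057717	53059957	67.9
ACADVL	19	27568181	27573378	47.1
PPP1R3B	27	24316623	24317477	34.3
GALE	2	129706509	129711871	121.9
PKLR	3	15396974	15408994	25.7
ANGPTL4	7	18236482	18243588	20.6
CDKN1A	23	10551755	10568782	14.1
ODC1	11	87175389	87182661	95.0
LPIN1	11	86050742	86128538	93.8
DUSP1	20	4449106	4452189	5.5
LMNA	3	14695234	14724663	24.1
APOA1	15	27932198	27934085	NA
ABCG8	11	26156365	26175034	NA
APOA4	15	27906598	27919592	NA
SAA1	29	26696726	26714918	NA
PC	29	45508279	45611042	NA
SDS	17	63302876	63311105	NA
FBP2	8	82396095	82438817	NA
SGLT1	17	72690558	72741954	NA
GK	X	118110570	118186827	NA
CYP7A1	14	26348324	26358692	NA
IGF-1R	21	7967718	8268246	NA
GADD45B	7	22411968	22414079	NA
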