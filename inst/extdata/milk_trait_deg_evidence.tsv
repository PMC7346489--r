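# Differential-expression evidence for the screened genes: the lactation-
# stage comparison(s) in which each gene was selected and its direction.
# Comparison assignment of single flags follows column order in the source
# table (early vs dry, peak vs dry, peak vs early).
gene	comparison	direction
APOC2	EARLY_VS_DRY	UP
ACADVL	EARLY_VS_DRY	UP
PPP1R3B	EARLY_VS_DRY	DOWN
GALE	EARLY_VS_DRY	UP
PKLR	EARLY_VS_DRY	DOWN
ANGPTL4	EARLY_VS_DRY	UP
ANGPTL4	PEAK_VS_DRY	UP
CDKN1A	EARLY_VS_DRY	DOWN
CDKN1A	PEAK_VS_DRY	UP
ODC1	EARLY_VS_DRY	UP
ODC1	PEAK_VS_DRY	UP
LPIN1	EARLY_VS_DRY	UP
LPIN1	PEAK_VS_DRY	UP
DUSP1	EARLY_VS_DRY	UP
LMNA	EARLY_VS_DRY	UP
APOA1	EARLY_VS_DRY	UP
APOA1	PEAK_VS_DRY	DOWN
ABCG8	EARLY_VS_DRY	DOWN
APOA4	EARLY_VS_DRY	UP
APOA4	PEAK_VS_DRY	UP
SAA1	EARLY_VS_DRY	UP
SAA1	PEAK_VS_DRY	UP
PC	EARLY_VS_DRY	UP
SDS	EARLY_VS_DRY	UP
FBP2	EARLY_VS_DRY	UP
FBP2	PEAK_VS_DRY	UP
SGLT1	EARLY_VS_DRY	DOWN
GK	EARLY_VS_DRY	UP
CYP7A1	EARLY_VS_DRY	UP
CYP7A1	PEAK_VS_DRY	UP
IGF-1R	EARLY_VS_DRY	DOWN
IGF-1R	PEAK_VS_DRY	DOWN
GADD45B	EARLY_VS_DRY	UP
GADD45B	PEAK_VS_DRY	UP
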