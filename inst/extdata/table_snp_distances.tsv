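# Published gene-to-SNP distances, one row per reported (gene, SNP) pair,
# with the distance label exactly as printed (mixed Kb/Mb units and
# decimal precisions preserved).
gene	snp_name	printed_label
APOA1	BTB-00590603	1.77 Mb
APOA1	BTB-00590405	3.59 Mb
ABCG8	BTB-00470332	1.34 Mb
ABCG8	BFGL-NGS-115431	1.78 Mb
ABCG8	BTB-01556917	2.46 Mb
ABCG8	Hapmap59290-rs29022016	2.56 Mb
ABCG8	BFGL-NGS-116483	3.49 Mb
ABCG8	ARS-BFGL-NGS-43804	3.57 Mb
ABCG8	ARS-BFGL-NGS-100459	4.03 Mb
APOC2	BFGL-NGS-117985	888.61 Kb
APOC2	Hapmap41540-BTA-43915	910.9 Kb
APOC2	Hapmap47618-BTA-43817	2.83 Mb
APOC2	ARS-BFGL-NGS-98028	4.11 Mb
APOA4	BTB-00590603	1.78 Mb
APOA4	BTB-00590405	3.61 Mb
SAA1	ARS-BFGL-NGS-24998	6.41 Kb
SAA1	UA-IFASA-8605	4.19 Mb
PC	ARS-BFGL-NGS-2893	2.89 Mb
PC	Hapmap40456-BTA-66218	3.28 Mb
PC	BFGL-NGS-117323	3.75 Mb
PPP1R3B	ARS-BFGL-NGS-43776	259.32 Kb
PPP1R3B	BTB-01063707	4.07 Mb
GALE	BTA-31250-no-rs	1.27 Mb
SDS	BFGL-NGS-110646	162.16 Kb
SDS	Hapmap52830-rs29014800	230.59 Kb
SDS	BTB-00682411	1.41 Mb
SDS	BTB-01992588	1.76 Mb
SDS	ARS-BFGL-NGS-17192	2.93 Mb
SDS	ARS-BFGL-NGS-34106	3.31 Mb
SDS	Hapmap40427-BTA-41914	3.36 Mb
FBP2	BTA-14515-no-rs	1.45 Mb
FBP2	ARS-BFGL-NGS-20324	3.95 Mb
PKLR	UA-IFASA-8925	1.31 Mb
SGLT1	BTA-90512-no-rs	3.96 Mb
GK	Hapmap34068-BES2_Contig513_1168	2.14 Mb
GK	BTA-30585-no-rs	2.47 Mb
GK	Hapmap39109-BTA-30591	2.50 Mb
GK	Hapmap33343-BTA-111447	2.89 Mb
GK	BTA-98858-no-rs	3.41 Mb
GK	Hapmap45528-BTA-102311	3.79 Mb
CYP7A1	ARS-BFGL-BAC-12159	3.76 Mb
CYP7A1	ARS-BFGL-NGS-3198	4.41 Mb
ANGPTL4	Hapmap23865-BTA-111820	1.84 Mb
ANGPTL4	BFGL-NGS-119066	4.60 Mb
ANGPTL4	ARS-BFGL-NGS-109534	4.63 Mb
ANGPTL4	BFGL-NGS-111315	4.65 Mb
IGF-1R	ARS-BFGL-NGS-10704	769.19 Kb
IGF-1R	ARS-BFGL-NGS-77061	1.07 Mb
CDKN1A	BFGL-NGS-115177	2.68 Mb
CDKN1A	ARS-BFGL-NGS-41214	3.28 Mb
CDKN1A	ARS-BFGL-NGS-17887	4.20 Mb
ODC1	BTA-110370-no-rs	74.93 Kb
ODC1	BFGL-NGS-114578	96.35 Kb
ODC1	ARS-BFGL-NGS-42014	197.94 Kb
ODC1	ARS-BFGL-NGS-17731	249.36 Kb
ODC1	Hapmap53648-rs29021240	605.73 Kb
ODC1	ARS-BFGL-NGS-70263	641.51 Kb
ODC1	ARS-BFGL-NGS-41670	789.42 Kb
ODC1	ARS-BFGL-BAC-16207	817.29 Kb
ODC1	Hapmap52066-rs29015690	2.02 Mb
ODC1	ARS-BFGL-NGS-28030	2.16 Mb
ODC1	Hapmap31724-BTA-126967	2.19 Mb
ODC1	ARS-BFGL-NGS-2015	2.30 Mb
ODC1	ARS-BFGL-NGS-104652	2.35 Mb
ODC1	ARS-BFGL-NGS-63978	3.54 Mb
ODC1	Hapmap40477-BTA-105881	3.65 Mb
ODC1	Hapmap56387-rs29014077	4.19 Mb
ODC1	ARS-BFGL-NGS-93601	4.25 Mb
ODC1	Hapmap46768-BTA-117394	4.53 Mb
GADD45B	Hapmap49309-BTA-78604	2.24 Mb
LPIN1	ARS-BFGL-NGS-14236	2.38 Kb
LPIN1	Hapmap53648-rs29021240	441.12 Kb
LPIN1	ARS-BFGL-NGS-17731	797.49 Kb
LPIN1	Hapmap52066-rs29015690	897.17 Kb
LPIN1	BTA-110370-no-rs	1.13 Mb
LPIN1	BFGL-NGS-114578	1.15 Mb
LPIN1	ARS-BFGL-NGS-2015	1.18 Mb
LPIN1	ARS-BFGL-NGS-104652	1.22 Mb
LPIN1	ARS-BFGL-NGS-42014	1.25 Mb
LPIN1	ARS-BFGL-NGS-70263	1.70 Mb
LPIN1	ARS-BFGL-NGS-41670	1.84 Mb
LPIN1	ARS-BFGL-BAC-16207	1.87 Mb
LPIN1	ARS-BFGL-NGS-63978	2.41 Mb
LPIN1	Hapmap40477-BTA-105881	2.52 Mb
LPIN1	Hapmap56387-rs29014077	3.07 Mb
LPIN1	ARS-BFGL-NGS-93601	3.13 Mb
LPIN1	ARS-BFGL-NGS-28030	3.21 Mb
LPIN1	Hapmap31724-BTA-126967	3.24 Mb
LPIN1	Hapmap46768-BTA-117394	3.41 Mb
LPIN1	ARS-BFGL-NGS-105586	4.21 Mb
LPIN1	ARS-BFGL-NGS-52709	4.23 Mb
DUSP1	ARS-BFGL-NGS-48030	44.19 Kb
DUSP1	Hapmap54098-rs29010434	53.45 Kb
DUSP1	Hapmap49207-BTA-51446	3.32 Mb
DUSP1	Hapmap36217-SCAFFOLD290026_2168	3.50 Mb
DUSP1	ARS-BFGL-NGS-27058	3.74 Mb
LMNA	UA-IFASA-8925	0.61 Mb
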