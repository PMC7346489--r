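# Significant GWAS SNPs for the five milk production traits near the
# screened genes (UMD3.1.80 positions). traits is the comma-separated set
# of associated trait codes; p_min/p_max bound the printed raw p values.
snp_name	chrom	pos_bp	traits	p_min	p_max
BTB-00590603	15	29702877	FY,PY,FP,PP	7.05E-22	4.71E-16
BTB-00590405	15	31527773	FY,PY	4.12E-11	1.22E-10
BTB-00470332	11	27519615	FY,PY	3.66E-09	1.25E-08
BFGL-NGS-115431	11	24379969	MY,FY,PY,FP,PP	3.18E-29	1.92E-07
BTB-01556917	11	23700685	PP	3.46E-12	3.46E-12
Hapmap59290-rs29022016	11	23599074	PY,PP	1.87E-22	7.11E-08
BFGL-NGS-116483	11	22666445	MY,FY,PY,FP,PP	1.60E-24	1.14E-08
ARS-BFGL-NGS-43804	11	22588525	MY,FY,PY,FP	2.85E-26	5.15E-08
ARS-BFGL-NGS-100459	11	22128569	FY,PY,PP	1.03E-24	7.98E-08
BFGL-NGS-117985	18	53948569	MY,FY,PY,FP,PP	9.83E-55	1.71E-19
Hapmap41540-BTA-43915	18	53970861	FY,PY,FP	3.07E-18	2.19E-09
Hapmap47618-BTA-43817	18	55892476	PP	1.07E-08	1.07E-08
ARS-BFGL-NGS-98028	18	57174711	FY,PY,FP,PP	1.40E-21	1.04E-10
ARS-BFGL-NGS-24998	29	26721324	PP	2.96E-08	2.96E-08
UA-IFASA-8605	29	30901735	FY,FP,PP	1.50E-16	1.50E-07
ARS-BFGL-NGS-2893	29	48501273	FY,PY,FP,PP	1.98E-12	8.87E-08
Hapmap40456-BTA-66218	29	48895237	FY	1.35E-08	1.35E-08
BFGL-NGS-117323	29	49357135	MY,FY,PY,FP	4.32E-19	3.58E-08
ARS-BFGL-NGS-43776	27	24576801	MY,FY,PY,FP,PP	6.30E-26	1.20E-07
BTB-01063707	27	28386241	MY,FY,PY,FP,PP	1.55E-45	1.35E-17
BTA-31250-no-rs	2	128437731	PY,FP,PP	1.26E-24	3.25E-08
BFGL-NGS-110646	17	63140712	FY,PY,FP,PP	2.61E-14	3.54E-08
Hapmap52830-rs29014800	17	63541690	FP,PP	4.31E-11	3.38E-07
BTB-00682411	17	61891068	PP	2.65E-08	2.65E-08
BTB-01992588	17	65071599	MY,FY,PY	3.55E-15	2.01E-10
ARS-BFGL-NGS-17192	17	66236750	MY,PY	2.97E-15	1.30E-12
ARS-BFGL-NGS-34106	17	66619908	FY,FP,PP	4.65E-25	3.68E-14
Hapmap40427-BTA-41914	17	66671839	FP,PP	6.15E-19	3.07E-11
BTA-90512-no-rs	17	68732546	FP,PP	6.81E-19	4.33E-13
BTA-14515-no-rs	8	83888935	FY,PY,PP	6.36E-12	7.78E-09
ARS-BFGL-NGS-20324	8	86384898	FY,PY,FP,PP	7.96E-22	3.80E-14
UA-IFASA-8925	3	14084731	PY	3.48E-07	3.48E-07
Hapmap34068-BES2_Contig513_1168	X	115968607	MY,FY,PY,FP,PP	2.30E-27	6.86E-09
BTA-30585-no-rs	X	120654979	FY,FP,PP	2.02E-16	1.36E-08
Hapmap39109-BTA-30591	X	120691496	FP,PP	6.01E-13	1.28E-07
Hapmap33343-BTA-111447	X	121076442	FY,PY,FP,PP	6.03E-13	7.03E-08
BTA-98858-no-rs	X	121600055	FY,FP,PP	7.03E-21	1.01E-09
Hapmap45528-BTA-102311	X	114319576	FY,FP,PP	3.01E-18	5.13E-09
ARS-BFGL-BAC-12159	14	22587081	MY,FY,PY,PP	4.94E-24	6.01E-11
ARS-BFGL-NGS-3198	14	21933950	FY,PY,FP,PP	1.21E-25	1.45E-12
Hapmap23865-BTA-111820	7	16397706	PP	1.51E-08	1.51E-08
BFGL-NGS-119066	7	13632174	FP,PP	9.49E-20	7.48E-10
ARS-BFGL-NGS-109534	7	13608935	FP,PP	8.42E-20	1.94E-09
BFGL-NGS-111315	7	13584721	FY,PY,FP,PP	4.90E-29	7.03E-12
Hapmap49309-BTA-78604	7	24655689	PP	4.34E-14	4.34E-14
ARS-BFGL-NGS-10704	21	9037431	FP,PP	2.60E-13	4.77E-08
ARS-BFGL-NGS-77061	21	6900116	PP	9.32E-10	9.32E-10
BFGL-NGS-115177	23	7874236	MY,FY,PY	1.83E-24	6.49E-17
ARS-BFGL-NGS-41214	23	13846320	MY,FY,PY,PP	2.10E-24	3.13E-11
ARS-BFGL-NGS-17887	23	14769068	MY,FY,PY,PP	3.76E-24	6.86E-09
BTA-110370-no-rs	11	87257595	FY,PY,FP	3.10E-12	2.68E-07
BFGL-NGS-114578	11	87279008	FY,PY	2.85E-11	1.82E-08
ARS-BFGL-NGS-42014	11	87380604	FY	9.34E-09	9.34E-09
ARS-BFGL-NGS-17731	11	86926025	FY,PY,FP	3.31E-16	3.55E-07
Hapmap53648-rs29021240	11	86569656	FY,PY	1.00E-10	2.14E-08
ARS-BFGL-NGS-70263	11	87824167	MY,FY,PY,PP	1.16E-17	2.25E-08
ARS-BFGL-NGS-41670	11	87972079	FY,PP	1.41E-08	2.53E-07
ARS-BFGL-BAC-16207	11	87999946	FY,PY,FP,PP	4.08E-10	3.65E-07
Hapmap52066-rs29015690	11	85153576	FY	1.10E-07	1.10E-07
ARS-BFGL-NGS-28030	11	89338824	FY,PY	2.08E-12	1.33E-07
Hapmap31724-BTA-126967	11	89371911	FY,PY,FP	1.05E-15	1.43E-08
ARS-BFGL-NGS-2015	11	84872349	FY,PY,FP,PP	1.83E-18	6.84E-05
ARS-BFGL-NGS-104652	11	84828071	MY,FY,PY	1.05E-18	2.22E-09
ARS-BFGL-NGS-63978	11	83637998	FY,PY,FP,PP	2.27E-15	1.78E-07
Hapmap40477-BTA-105881	11	83526455	FY,PY,FP,PP	1.80E-24	2.41E-11
Hapmap56387-rs29014077	11	82982779	FY	1.25E-07	1.25E-07
ARS-BFGL-NGS-93601	11	82920732	FY,PY,FP,PP	1.88E-21	2.96E-13
Hapmap46768-BTA-117394	11	82643114	MY,FY,PY	1.78E-13	1.73E-07
ARS-BFGL-NGS-14236	11	86048363	FY,PY	1.29E-12	4.60E-08
ARS-BFGL-NGS-105586	11	81845043	FY,PY,FP	2.47E-15	3.00E-08
ARS-BFGL-NGS-52709	11	81819453	FY,PY,FP,PP	3.01E-25	1.28E-08
ARS-BFGL-NGS-48030	20	4496376	PP	2.07E-08	2.07E-08
Hapmap54098-rs29010434	20	4395656	FY,PY,PP	1.35E-12	1.66E-08
Hapmap49207-BTA-51446	20	7770495	MY,FY,PY,FP,PP	5.02E-27	9.06E-11
Hapmap36217-SCAFFOLD290026_2168	20	7954374	FY,PY	7.19E-09	7.36E-09
ARS-BFGL-NGS-27058	20	712232	FY,PY,FP	1.11E-10	3.92E-07
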