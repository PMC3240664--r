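# Reference genome-wide fragment length-class counts per protein
# (published study, modENCODE-derived tracks), classes in kb.
# Printed percentages are carried for cross-checking the percent machinery.
protein	n_1_3	n_4_6	n_7_9	n_10_11	pct_1_3	pct_4_6	pct_7_9	pct_10_11
RNA pol II	4760	1288	396	111	72.6	19.6	6.0	1.7
CHRIZ	3045	1103	264	89	67.7	24.5	5.9	2.0
WDS	4639	484	41	4	89.8	9.4	0.8	0.1
ORC2	4178	651	108	16	84.4	13.1	2.2	0.3
H1_dip	3543	796	237	68	76.3	17.1	5.1	1.5
PC	1491	373	138	52	72.6	18.2	6.7	2.5
GAF	2909	591	110	16	80.2	16.3	3.0	0.4
CP190	4982	714	81	11	86.1	12.3	1.4	0.2
BEAF-32	4060	499	53	4	88.0	10.8	1.1	0.1
CTCF	1446	405	62	7	75.3	21.1	3.2	0.4
MOD(MDG4)	843	9	0	0	98.9	1.1	0.0	0.0
Su(Hw)	2829	1020	178	36	69.6	25.1	4.4	0.9
dMi-2	3802	625	118	23	83.2	13.7	2.6	0.5
NURF301	5336	680	101	13	87.0	11.1	1.6	0.2
BRE1	5245	675	54	7	87.7	11.3	0.9	0.1
Trx-C	4885	319	16	0	93.6	6.1	0.3	0.0
dRing	2019	198	55	13	88.4	8.7	2.4	0.6
E(Z)	760	113	27	9	83.6	12.4	3.0	1.0
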