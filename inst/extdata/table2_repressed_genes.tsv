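gene_id	fold_change	q
PRAS40	3.1092	0.0000887
SLC7A5	2.7426	0.0001686
CSF1	2.5244	0.00004997
RRP1B	2.3603	0.00006787
SEMA7A	2.3251	0.0013856
ADAM19	2.3148	0.00003501
TNFSF18	2.3009	0.0005973
CARM1	2.2891	0.00004997
POM121	2.2415	0.00006787
SH3GL1	2.2386	0.00003501
S100A16	2.2311	0.00003501
KLC2	2.2168	0.00003501
PPAP2B	2.1852	0.00007764
PLBD2	2.1415	0.00003501
CYB5R3	2.0392	0.00006787
LASP1	2.0308	0.00003501
PPP6R1	2.0175	0.00003501
CDC25A	2.0013	0.0004932
PNO1	1.9322	0.0011347
HAS2	1.9214	0.0014053
SEPT9	1.9143	0.0001192
MYADM	1.9084	0.0001448
PLAGL2	1.9068	0.00019
GSK3A	1.902	0.00006787
AKT2	1.9014	0.00004997
REXO1	1.8962	0.0004027
FSCN1	1.8733	0.0004771
STK40	1.8697	0.00008406
IL7R	1.8555	0.0064985
TMEM45A	1.8489	0.0064985
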