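model	survival_model	ctd_mean	ctd_sd	ibs_mean	ibs_sd
mlp	logistic_hazard	0.5543	0.0689	0.3183	0.0497
gcn	logistic_hazard	0.6309	0.0481	0.2331	0.0358
sage	logistic_hazard	0.6247	0.0505	0.2331	0.0389
gat	logistic_hazard	0.6352	0.0520	0.2341	0.0365
mlp	pmf	0.5941	0.0629	0.2324	0.0222
gcn	pmf	0.6265	0.0493	0.2130	0.0231
sage	pmf	0.6378	0.0415	0.2140	0.0238
gat	pmf	0.6339	0.0451	0.2154	0.0229
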