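model	survival_model	ctd_mean	ctd_sd	ibs_mean	ibs_sd
mlp	logistic_hazard	0.6581	0.0559	0.2577	0.0902
gcn	logistic_hazard	0.7077	0.0373	0.1965	0.0240
sage	logistic_hazard	0.7099	0.0409	0.1955	0.0269
gat	logistic_hazard	0.6962	0.0362	0.2018	0.0260
mlp	pmf	0.6455	0.0516	0.2022	0.0174
gcn	pmf	0.6785	0.0464	0.1964	0.0195
sage	pmf	0.6868	0.0470	0.1859	0.0222
gat	pmf	0.6720	0.0500	0.1958	0.0233
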