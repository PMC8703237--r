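phenotype	n_samples	n_cohorts	n_true	prevalence_pct	auc_cv	auc_lobov
low_egfr	21439	23	1196	5.6	0.99	0.97
high_triglycerides	13401	11	1645	12.3	0.97	0.95
high_ldl_chol	13261	11	2051	15.5	0.96	0.97
high_totchol	16586	11	3206	19.3	0.96	0.96
low_hdl_chol	16506	11	7414	44.9	0.95	0.95
diabetes	18841	16	4034	21.4	0.94	0.86
metabolic_syndrome	7811	6	3452	44.2	0.93	0.86
sex	21610	23	10281	47.6	0.92	0.91
lipid_medication	17707	14	5783	32.7	0.91	0.85
low_age	21519	23	3353	15.6	0.89	0.80
high_hscrp	5180	8	1548	29.9	0.86	0.81
blood_pressure_lowering_med	15832	13	7234	45.7	0.82	0.71
high_age	21519	23	8273	38.4	0.82	0.73
obesity	19322	18	3135	16.2	0.78	0.76
low_hgb	10508	6	1299	12.4	0.76	0.72
low_wbc	9496	6	818	8.6	0.73	0.61
current_smoking	21662	23	8276	38.2	0.71	0.63
alcohol_consumption	16430	13	11763	71.6	0.71	0.60
middle_age	21519	23	9893	46.0	0.71	0.58
high_pressure	17509	12	7765	44.3	0.68	0.60
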