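subject_id	analyte_id	dose_mg	ke	t_half	t_half_digits	tmax	cmax	auc_0_t	auc_0_inf
patient1	CLP	75	0.81	0.85	2	0.25	0.1	0.85	0.85
patient1	CCA	75	0.15	4.51	2	1	4.2	17.79	20.46
patient1	ATV	20	0.08	8.15	2	3	0.09	0.67	1.03
patient2	CLP	75	0.58	1.20	2	0.25	0.08	0.63	0.63
patient2	CCA	75	0.23	3	0	1.24	4.77	19.61	21.55
patient2	ATV	40	0.08	8.37	2	2.52	0.15	0.91	0.96
patient3	CLP	75	1.02	0.68	2	0.25	0.07	0.65	0.65
patient3	CCA	75	0.13	5.21	2	1	3.32	14.38	15.45
patient3	ATV	80	0.07	9.32	2	3.06	0.19	1.32	1.36
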