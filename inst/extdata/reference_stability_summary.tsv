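analyte_id	condition	nominal	mean_found	sd	recovery_pct	rsd_pct	n
CCA	short_term	0.12	0.11	0.01	92	9.09	3
CCA	short_term	4	3.86	0.15	97	3.89	3
CCA	long_term	0.12	0.11	0.01	92	9.08	3
CCA	long_term	4	3.85	0.06	96	1.56	3
ATV	short_term	0.5	0.47	0.01	94	2.13	3
ATV	short_term	2.5	2.41	0.02	96	0.83	3
ATV	long_term	0.5	0.46	0.05	92	10.87	3
ATV	long_term	2.5	2.41	0.01	96	0.42	3
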