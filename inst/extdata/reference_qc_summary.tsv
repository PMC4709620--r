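analyte_id	period	nominal	mean_found	sd	recovery_pct	rsd_pct	n
CLP	intraday	0.25	0.24	0.01	96	4.17	3
CLP	intraday	0.50	0.49	0.02	98	4.08	3
CLP	intraday	1	0.97	0.02	97	2.06	3
CLP	intraday	2	1.97	0.04	98	2.03	3
CLP	interday	0.25	0.24	0.02	96	8.33	3
CLP	interday	0.50	0.48	0.01	96	2.08	3
CLP	interday	1	0.96	0.02	96	2.08	3
CLP	interday	2	1.94	0.05	97	2.57	3
CCA	intraday	0.5	0.47	0.02	94	4.26	3
CCA	intraday	1	0.95	0.01	95	1.05	3
CCA	intraday	2	1.96	0.02	98	1.02	3
CCA	intraday	4	3.87	0.08	97	2.07	3
CCA	interday	0.50	0.47	0.01	94	2.12	3
CCA	interday	1	0.96	0.01	96	1.04	3
CCA	interday	2	1.95	0.03	98	1.54	3
CCA	interday	4	3.88	0.08	97	2.06	3
ATV	intraday	0.20	0.18	0.01	90	5.55	3
ATV	intraday	0.3	0.28	0.01	93	3.57	3
ATV	intraday	1	0.97	0.01	97	1.03	3
ATV	intraday	2.5	2.44	0.03	98	1.23	3
ATV	interday	0.20	0.18	0.01	90	5.56	3
ATV	interday	0.30	0.29	0.02	97	6.90	3
ATV	interday	1	0.98	0.05	98	5.10	3
ATV	interday	2.5	2.47	0.01	99	0.40	3
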