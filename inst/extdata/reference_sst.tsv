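analyte_id	retention_time	tailing_factor	plate_count	resolution
CCA	9.66	0.94	14763	8.75
ATV	10.99	1.12	15935	NA
CLP	12.68	1.5	18340	8.82
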