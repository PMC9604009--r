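taxon	family_id	daughter_age	rel_abund_daughter	mother_age	rel_abund_mother	substitution_rate
Ca_Lachnocurva_vaginae	21	18	9.21	41	2.80	1.48e-05
Atopobium_vaginae	30	14	2.22	42	0.46	1.05e-06
Clostridiales_family	5	14	2.15	36	2.31	5.18e-06
Gardnerella	30	14	47.42	42	16.56	1.98e-05
Lactobacillus_crispatus	3	15	44.54	32	72.13	4.00e-06
Lactobacillus_crispatus	1	15	80.91	NA	75.57	9.48e-06
Lactobacillus_crispatus	5	14	31.88	36	39.26	6.26e-06
Lactobacillus_iners	30	14	12.34	42	5.36	8.32e-06
Prevotella_timonensis	41	15	16.16	47	1.63	7.50e-06
Prevotella_timonensis	5	14	2.18	36	2.83	3.24e-05
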