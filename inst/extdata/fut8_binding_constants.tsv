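ligand	Kd_uM	Kd_se	dG	dG_se	dH	dH_se	minusTdS	minusTdS_se	n	measurable
GDP	6.1	1.4	-7.09	1.65	-5.02	0.4	-2.07	0.48	0.60	TRUE
G0 (excess GDP)	8	1.3	-6.89	1.11	-2.42	0.15	-4.47	0.72	1.2	TRUE
G0 (without GDP)	318	134	-4.75	2	8.35	4.05	-13.1	6.35	1.6	TRUE
G0-peptide (excess GDP)	10	4	-6.82	2.6	-3.2	0.56	-3.62	0.99	0.84	TRUE
M3N2-peptide (excess GDP)	406	159	-4.6	1.8	7.7	1.9	-12.3	4.8	1.6	TRUE
M3N2 (excess GDP)	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE
M5N2-Asn (excess GDP)	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE
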