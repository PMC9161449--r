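substrate	Km_uM	Km_se	Vmax	Vmax_se	kcat	kcat_se	efficiency	saturable	note
GDP-Fuc	14.56	3.4	244.3	13.1	14.17	0.76	0.97	TRUE	donor; determined at saturating G0
G0	113.1	15.43	282.1	11.72	15.62	0.5	0.14	TRUE	acceptor
G0-peptide	133.1	19.99	224.7	10.68	13.03	0.62	0.1	TRUE	acceptor
M3N2	NA	NA	NA	NA	NA	NA	NA	FALSE	not active
M3N2-peptide	NA	NA	NA	NA	NA	NA	NA	FALSE	linear velocity vs concentration; not saturable
M5N2-Asn	NA	NA	NA	NA	NA	NA	NA	FALSE	linear velocity vs concentration; not saturable
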