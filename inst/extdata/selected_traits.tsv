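strain_id	taxonomy	NH4	PPU	PPU_se	PSI	SID	SID_se	NH3	NH3_se	KSI	BF	EPS	EPS_se	EPS_peg18	EPS_peg18_se	IAA	IAA_se	IAA_peg18	IAA_peg18_se
UC4449	Pseudomonas glycinis	TRUE	48.35	0.03	15.5	44.24	0.07	53.11	11.10	37	FALSE	0.23	0.01	3.59	0.14	27.30	1.40	26.0	0.24
UC4450	Enterobacter ludwigi	TRUE	35.56	0.04	10	71.43	0.04	102.0	14.74	16	TRUE	0.03	0.01	4.82	0.09	46.51	1.00	24.19	0.61
UC4521	Bacillus licheniformis	TRUE	35.59	0.04	32	18.37	0.05	111.2	17.45	32	TRUE	0.35	0.02	1.20	0.23	16.29	1.35	7.64	0.04
UC4439	Pseudomonas frederiksbergensis	TRUE	50.65	0.02	19	62.09	0.06	64.86	14.35	14	FALSE	0.18	0.01	3.93	0.95	13.58	1.37	22.82	0.75
UC4553	Pseudomonas plecoglossicida	TRUE	48.77	0.03	32	69.26	0.05	44.50	16.52	32	FALSE	0.06	0.01	2.13	0.32	8.59	2.00	16.75	1.42
UC4478	Pseudomonas chlororaphis	TRUE	53.18	0.03	7	79.61	0.02	65.88	24.74	7	FALSE	0.72	0.01	4.16	0.36	17.40	0.32	27.25	1.91
UC4510	Priestia megaterium	TRUE	47.65	0.04	16	38.09	0.05	16.37	2.30	16	FALSE	0.12	0.01	0.93	0.30	15.42	1.13	8.68	0.42
UC4490	Serratia rhizosphaerae	TRUE	65.74	0.02	25	0.93	0.06	34.54	8.56	25	TRUE	0.09	0.01	1.48	0.03	10.56	1.17	11.44	0.48
UC4535	Pseudomonas furukawaii	TRUE	32.58	0.07	6	52.27	0.05	52.49	10.32	6	FALSE	0.08	0.04	3.30	0.26	8.38	2.10	11.73	0.87
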