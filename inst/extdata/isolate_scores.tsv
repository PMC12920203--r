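strain_id	taxonomy	NH4	KS	PS_plate	PS_broth	SID	NH3	EPS	BF	IAA	DT	n_trait	d_trait	total	selected
UC4449	Pseudomonas glycinis	1	1	1	1	0.75	0.5	1	1	0.5	0.5	5.25	3	8.25	TRUE
UC4489	Pseudomonas aeruginosa	1	1	0.75	1	1	0.5	0.75	0	0	1	5.25	1.75	7	FALSE
UC4450	Enterobacter ludwigi	1	0.75	0.75	0.5	1	1	0	0	1	0.75	5	1.75	6.75	TRUE
UC4521	Bacillus licheniformis	0.75	1	0	0.25	1	1	1	1	0	0.5	4	2.5	6.5	TRUE
UC4441	Pantoea stewartii	1	1	0.5	1	0.75	0	0.75	1	0.25	0.25	4.25	2.25	6.5	FALSE
UC4439	Pseudomonas frederiksbergensis	1	0.25	1	0.75	0.75	0.5	1	1	0	0.25	4.25	2.25	6.5	TRUE
UC4553	Pseudomonas plecoglossicida	1	1	0.5	0.75	1	0.25	0.25	0	0	1	4.5	1.25	5.75	TRUE
UC4444	Bacillus velezensis	1	0	0.75	0.5	0.5	0.5	1	1	0.25	0.25	3.25	2.5	5.75	FALSE
UC4478	Pseudomonas chlororaphis	1	0	0.5	0.25	0.75	0.5	1	0	0.5	1	3	2.5	5.5	TRUE
UC4510	Priestia megaterium	1	0.25	0	0.75	1	0	0.5	1	0.5	0.5	3	2.5	5.5	TRUE
UC4490	Serratia rhizosphaerae	1	0.75	0.75	1	0	0.25	0.5	0	0	1	3.75	1.5	5.25	TRUE
UC4535	Pseudomonas furukawaii	1	0	0	0.25	1	0.5	0.25	1	0.25	1	2.75	2.5	5.25	TRUE
UC4549	Pseudomonas furukawaii	1	0	0.75	0	0.75	0.25	0.25	1	0	0.75	2.75	2	4.75	FALSE
UC4479	Pseudomonas lini	1	0.75	0.5	0.75	0.5	0.25	1	0	0	0	3.75	1	4.75	FALSE
UC4443	Bacillus amyloliquefaciens	1	0	0.75	0	0.25	0.25	1	1	0	0.25	2.25	2.25	4.5	FALSE
UC4442	Cupriavidus necator	1	0	0.75	0.25	0	0.25	0.5	1	0	0.25	2.25	1.75	4	FALSE
UC4446	Bacillus amyloliquefaciens	1	0.25	0	0.5	0.5	0.5	1	0	0	0.25	2.75	1.25	4	FALSE
UC4481	Acinetobacter couvalinii	1	0.75	0.75	0.25	0.25	0.25	0.25	0	0	0.25	3.25	0.5	3.75	FALSE
UC4440	Bacillus atrophaeus	1	1	0.5	0.25	0	0	0.75	0	0	0.25	2.75	1	3.75	FALSE
UC4445	Kokuria rosea	1	0	0	0.25	1	0.25		1	0	0.25	2.5	1.25	3.75	FALSE
UC4526	Pseudomonas hibiscicola	1	0	0	0	0.75	0.5	0.5	0	0.25	0.5	2.25	1.25	3.5	FALSE
UC4527	Pseudomonas furukawaii	1	0.5	0	0.25	0.25	0.5	0.25	0	0	0.75	2.5	1	3.5	FALSE
UC4545	Priestia megaterium	0.75	0.25	0	1	0.5	0.25	0.25	0	0	0.5	2.75	0.75	3.5	FALSE
UC4546	Priestia megaterium	0	0.25	0	1	0.25	0.5	0.25	1	0	0.25	2	1.5	3.5	FALSE
UC4460	Streptomyces albireticuli	0	0	0	0	0.25	0.25	1	1	0.5	0.5	0.5	3	3.5	FALSE
UC4495	Krasilnikoviella muralis	0.75	0	0.5	0.25	0	0	0.75	1	0	0.25	1.5	2	3.5	FALSE
UC4551	Pseudomonas boreopolis	1	1	0	0.5	0	0	0.5	0	0	0.25	2.5	0.75	3.25	FALSE
UC4484	Calidifontibacillus erzurumensis	0.5	0	0	0.5	0.5	0	1	0	0	0.75	1.5	1.75	3.25	FALSE
UC4498	Peribacillus simplex	0.75	0	0.75	0.25	0	0	0.75	0	0	0.75	1.75	1.5	3.25	FALSE
UC4533	Microbacterium foliorum	1	0.25	0	0	0	0.25	0.75	0	0	0.75	1.5	1.5	3	FALSE
UC4485	Empedobacter brevis	0	0	0.5	0	0	0	1	1	0.25	0.25	0.5	2.5	3	FALSE
UC4491	Sphingobacterium pakistanense	0	0	0.5	0.5	0	0.25	0.5	1	0	0.25	1.25	1.75	3	FALSE
UC4534	Pseudomonas furukawaii	1	0	0	0.25	0.25	0.5	0.5	0	0	0.25	2	0.75	2.75	FALSE
UC4461	Variovorax paradoxus	1	0	0.75	0	0	0.25	0	0	0	0.75	2	0.75	2.75	FALSE
UC4467	Paenibacillus susongensis	0.5	0	0.5	0	0	0.25	0	1	0	0.5	1.25	1.5	2.75	FALSE
UC4509	Sinorhizobium arboris	1	0.25	0	0	0	0.5	0	0	0.75	0	1.75	0.75	2.5	FALSE
UC4454	Streptomyces canus	0	0	0	0	0	0.25	0.5	0	1	0.5	0.25	2	2.25	FALSE
UC4492	Streptomyces violaceochromogenes	0	0	0	0	0	0.25	0.5	1	0	0.5	0.25	2	2.25	FALSE
UC4497	Streptomyces endophyticus	0.75	0	0	0.25	0	0	0.5	0	0	0.5	1	1	2	FALSE
UC4507	Rossellomorea marisflavi	0.5	0	0	0.25	0	0.25	0	0	0.25	0.75	1	1	2	FALSE
UC4516	Bacillus zanthoxyli	0	0	0	0.5	0.25	0	0	0	0.5	0.75	0.75	1.25	2	FALSE
UC4437	Streptomyces mauvecolor	0	0	0	0	0	0.25	1	0	0.25	0.5	0.25	1.75	2	FALSE
UC4548	Rhizobium wuzhouense	0	0	0	0	0	0.25	0.25	1	0	0.25	0.25	1.5	1.75	FALSE
UC4493	Streptomyces chartreusis	0	0	0	0.25	0	0.25	0.75	0	0	0.5	0.5	1.25	1.75	FALSE
UC4501	Cupriavidus cauae	1	0	0	0	0	0	0.25	0	0	0.25	1	0.5	1.5	FALSE
UC4554	Streptomyces arenae	0	0	0	0	0	0.25	0.75	0	0	0.5	0.25	1.25	1.5	FALSE
UC4556	Streptomyces albogriseolus	0	0	0	0	0	0.25	0.75	0	0	0.5	0.25	1.25	1.5	FALSE
UC4557	Streptomyces collinus	0	0	0	0	0	0.25	0.5	0	0	0.5	0.25	1	1.25	FALSE
UC4434	Streptomyces mauveocolor	0	0	0	0	0	0	0.75	0	0	0.5	0	1.25	1.25	FALSE
UC4511	Brevibacillus laterosporus	0	0	0	0	0	0	0.5	0	0	0.5	0	1	1	FALSE
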