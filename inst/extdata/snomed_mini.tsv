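code	display	parent_codes
410607006	Organism (organism)	
409822003	Domain Bacteria (organism)	410607006
112283007	Escherichia coli (organism)	409822003
56415008	Klebsiella pneumoniae (organism)	409822003
52499004	Pseudomonas aeruginosa (organism)	409822003
990001001	Pseudomonas aeruginosa fixture subspecies (organism)	52499004
3092008	Staphylococcus aureus (organism)	409822003
990001005	Acinetobacter baumannii (organism)	409822003
49872002	Virus (organism)	410607006
990002001	Fixture respiratory virus (organism)	49872002
84676004	Prion (organism)	410607006
414561005	Kingdom Fungi (organism)	410607006
990003001	Fixture yeast (organism)	414561005
370570004	Kingdom Protozoa (organism)	410607006
990004001	Fixture protozoan (organism)	370570004
990005001	Domain Archaea (organism)	410607006
990005002	Fixture archaeon (organism)	990005001
990006001	Kingdom Animalia (organism)	410607006
990006002	Fixture mite (organism)	990006001
990007001	Kingdom Plantae (organism)	410607006
990007002	Fixture plant (organism)	990007001
990008001	Kingdom Viridiplantae (organism)	410607006
990009001	Slime mold (organism)	410607006
409793007	Antimicrobial resistant bacteria (organism)	410607006
707497007	Carbapenem resistant bacteria (organism)	409793007
726492000	Carbapenem resistant Pseudomonas aeruginosa (organism)	707497007
115329001	Methicillin resistant Staphylococcus aureus (organism)	409793007
409795000	Antimicrobial resistant virus (organism)	410607006
409794001	Antimicrobial resistant fungi (organism)	410607006
260373001	Detected (qualifier value)	
260415000	Not detected (qualifier value)	
419984006	Inconclusive (qualifier value)	
10828004	Positive (qualifier value)	
260408008	Weakly positive (qualifier value)	
260385009	Negative (qualifier value)	
75540009	High (qualifier value)	
62482003	Low (qualifier value)	
260347006	Present + out of ++++ (qualifier value)	
260348001	Present ++ out of ++++ (qualifier value)	
260349009	Present +++ out of ++++ (qualifier value)	
260350009	Present ++++ out of ++++ (qualifier value)	
117259009	Microscopy (procedure)	
58586006	Microbial ova-parasite examination (procedure)	
117023006	Thick film peripheral blood smear (procedure)	
408195004	Thick film for malarial parasites (procedure)	
117024000	Thin film peripheral blood smear method (procedure)	
67047002	Microbial wet smear (procedure)	
27318003	Potassium hydroxide preparation (procedure)	
104157003	Light microscopy (procedure)	
73512001	Electron microscopic study (procedure)	
127790008	Staining method (procedure)	
67122001	Acid fast stain method (procedure)	127790008
990010001	Fixture differential stain method (procedure)	127790008
398545005	Nucleic acid assay (procedure)	
9718006	Polymerase chain reaction analysis (procedure)	
25231800	Immunology laboratory test (procedure)	
77559007	Immunologic avidity, function (observable entity)	
1285113001	Type of antimicrobial resistant organism (observable entity)	
4341000179107	Microbiology report (record artifact)	
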