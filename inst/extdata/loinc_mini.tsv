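code	display	property	method	class	component
11475-1	Microorganism identified in Specimen by Culture	Prid	Culture	MICRO	Microorganism
49223-1	Colony count [#/volume] in Unspecified specimen by Visual count	NCnc	Visual count	MICRO	Colony count
564-5	Colony count [#] in Unspecified specimen by Visual count	Num	Visual count	MICRO	Colony count
38436-2	Colony count [#/mass] in Unspecified specimen by Visual count	NCnt	Visual count	MICRO	Colony count
20774-6	Colony count [Units/volume] in Unspecified specimen by Visual count	ACnc	Visual count	MICRO	Colony count
18945-6	Methicillin [Susceptibility]	Susc		ABXBACT	Methicillin
99001-1	Piperacillin [Susceptibility]	Susc		ABXBACT	Piperacillin
99002-2	Cefotaxime [Susceptibility]	Susc		ABXBACT	Cefotaxime
99003-3	Meropenem [Susceptibility]	Susc		ABXBACT	Meropenem
99004-4	Ciprofloxacin [Susceptibility]	Susc		ABXBACT	Ciprofloxacin
99005-5	Meropenem [Susceptibility] by MIC	Susc	MIC	ABXBACT	Meropenem
99006-6	Methicillin resistance [Susceptibility] by Genotyping	Susc	Genotyping	ABXBACT	Methicillin resistance
92253-4	Microorganism identified in Isolate or Specimen by Molecular genetics method	Prid	Molecular genetics	MICRO	Microorganism
88603-6	Adenovirus Ag [Presence] in Lower respiratory specimen by Immunoassay	PrThr	Immunoassay	MICRO	Adenovirus Ag
99010-0	Cytomegalovirus IgG Ab [Presence] in Serum by Immunoassay	PrThr	Immunoassay	MICRO	Cytomegalovirus IgG Ab
72421-1	Vancomycin resistance vanB gene [Presence] by Molecular method	PrThr	Molecular	ABXBACT	vanB gene
99007-7	Carbapenemase blaKPC gene [Presence] by Molecular method	PrThr	Molecular	ABXBACT	blaKPC gene
92251-8	Microorganism gene detected [Presence] by Molecular method	PrThr	Molecular	MICRO	Microorganism gene
92246-8	Microorganism resistance mutation detected [Presence] by Molecular method	PrThr	Molecular	MICRO	Resistance mutation
99008-8	Shiga toxin 1 [Presence] in Isolate	PrThr		MICRO	Shiga toxin 1
99009-9	Clostridioides difficile toxin B [Presence] in Stool	PrThr		MICRO	Clostridioides difficile toxin B
75371-5	Bartlett score of Sputum Qualitative by Light microscopy	Score	Light microscopy	MICRO	Bartlett score
43391-2	Bacterial vaginosis score	Score		MICRO	Nugent score
99780-9	Multidrug resistant Gram-negative organism classification [Type]	Type		MICRO	MRGN classification
18725-2	Microbiology studies (set)	-		MICRO	Microbiology studies
92894-5	Microbiology - bacterial studies (set)	-		MICRO	Bacterial studies
92893-7	Microbiology - viral studies (set)	-		MICRO	Viral studies
96397-5	Microbiology - mycobacteriology studies (set)	-		MICRO	Mycobacteriology studies
96398-3	Microbiology - mycology studies (set)	-		MICRO	Mycology studies
92892-9	Microbiology - parasitic studies (set)	-		MICRO	Parasitic studies
LA33214-0	2MRGN	-			MRGN answer
LA33215-7	3MRGN	-			MRGN answer
LA33216-5	4MRGN	-			MRGN answer
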