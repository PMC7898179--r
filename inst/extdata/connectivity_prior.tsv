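kind	region_or_signal	ligand	genes	grouped
in	PVN	oxytocin	Oxtr	FALSE
in	PVN	vasopressin	Avpr1a;Avpr1b	FALSE
in	PVN	natriuretic peptide	Npr1;Npr2;Npr3	FALSE
in	RPa	serotonin	Htr2a;Htr3a;Htr3b;Htr6	FALSE
in	RPa	TRH	Trhr	FALSE
in	CeA	somatostatin	Sstr2;Sstr3	FALSE
in	CeA	CRH	Crhr1;Crhr2	FALSE
in	BST	CRH	Crhr1;Crhr2	FALSE
in	LHA	orexin	Hcrtr1;Hcrtr2	FALSE
in	TMN	histamine	Hrh1;Hrh3	FALSE
in	NTS/AP/CVLM/LC	dopamine	Drd1;Drd2;Drd4	TRUE
in	NTS/AP/CVLM/LC	GABA	Gabra1;Gabra2;Gabrb1;Gabbr1	TRUE
in	NTS/AP/CVLM/LC	norepinephrine	Adra1a;Adra2a;Adrb1	TRUE
out	ACh		Chat;Ache	FALSE
out	Dopa		Th;Ddc	FALSE
out	NE		Th;Ddc;Dbh	FALSE
out	Epi		Th;Ddc;Dbh;Pnmt	FALSE
out	GABA		Gad1;Gad2	FALSE
out	ANP		Nppa	FALSE
out	tachykinins		Tac1	FALSE
out	somatostatin		Sst	FALSE
out	CCK		Cck	FALSE
out	CART		Cartpt	FALSE
out	galanin		Gal	FALSE
out	follistatin-like 1		Fstl1	FALSE
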