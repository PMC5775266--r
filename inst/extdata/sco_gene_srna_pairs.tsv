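# Curated S. coelicolor screen: genes up-regulated in the RNase III (rnc)
# deletion mutant paired with antisense/adjacent small RNA genes
# (scr = small coelicolor RNA) from five published catalogs.
# category: printed orientation class; arrows: gene/sRNA strand notation,
# left-to-right along the genome (-> / <- gene, => / <= sRNA, * unknown).
gene_id	srna_id	source	category	arrows	comment
SCO0499	scr0500	Moody2013	ambiguous	-> * <-	mRNA up-regulated in rnc mutant
SCO0500	scr0500	Moody2013	ambiguous	-> * <-	mRNA up-regulated in rnc mutant
SCO1150	scr1150	Moody2013	cutoRNA	-> <= <-	mRNA up-regulated in rnc mutant
SCO1565	scr1566	Swiercz2008	ambiguous	<- * ->	predicted
SCO1626	scr1625	Moody2013	cutoRNA	-> <= <-	as1625 analyzed
SCO1630	scr1631	Swiercz2008	ambiguous	<- * <-	predicted
SCO1659	scr1659	Swiercz2008	ambiguous	-> * ->	predicted
SCO1700	scr1700	DAlia2010	cis_asRNA	<- => <-	predicted by RNAz
SCO1906	scr1907	Swiercz2008	ambiguous	<- * <-	predicted
SCO2197	scr2198	Swiercz2008	ambiguous	<- * ->	predicted
SCO2198	scr2198	DAlia2010	cis_asRNA	<- <= ->	confirmed, as2198 analyzed
SCO3003	scr3004	Swiercz2008	ambiguous	<- * ->	predicted
SCO3113	scr3114	Swiercz2008	ambiguous	-> * <-	predicted
SCO3132	scr3133	DAlia2010	cis_asRNA	-> <= <-	predicted by RNAz
SCO3216	scr3216	Swiercz2008	ambiguous	<- * ->	predicted
SCO3217	scr3217	Swiercz2008	ambiguous	-> * ->	predicted
SCO4095	scr4096	Swiercz2008	ambiguous	-> * ->	predicted
SCO4142	scr4143	Swiercz2008	ambiguous	<- * <-	predicted
SCO4144	scr4145	Swiercz2008	ambiguous	<- * <-	predicted
SCO4145	scr4145	Swiercz2008	ambiguous	<- * <-	predicted
SCO4145	scr4146	Swiercz2008	ambiguous	<- * ->	predicted
SCO4229	scr4229	Swiercz2008	ambiguous	<- * ->	predicted
SCO4249	scr4249	Swiercz2008	ambiguous	<- * ->	predicted
SCO4283	scr4283	Moody2013	cutoRNA	-> <= <-	mRNA up-regulated in rnc mutant
SCO4698	scr4699	Moody2013	ambiguous	-> <= ->	predicted
SCO4748	scr4749	Moody2013	cutoRNA	-> => <-	mRNA up-regulated in rnc mutant
SCO4882	scr4883	Swiercz2008	ambiguous	-> * ->	predicted
SCO4947	scr4947	Swiercz2008	ambiguous	-> * ->	predicted
SCO5106	scr5106	Moody2013	cutoRNA	-> => <-	mRNA up-regulated in rnc mutant
SCO5112	scr5112	Swiercz2008	cis_asRNA	-> * ->	predicted, as5112 analyzed
SCO5142	scr5143	Moody2013	ambiguous	-> <= ->	predicted
SCO5145	scr5145	Swiercz2008	ambiguous	<- * ->	predicted
SCO5145	scr5146	Moody2013	cutoRNA	-> => <-	mRNA up-regulated in rnc mutant
SCO5163	scr5164	Swiercz2008	ambiguous	<- * ->	predicted
SCO5476	scr5476	Swiercz2008	ambiguous	-> * ->	predicted
SCO5519	scr5518	Moody2013	ambiguous	<- * ->	predicted
SCO5520	scr5521	Swiercz2008	ambiguous	-> * ->	predicted
SCO5521	scr5521	Swiercz2008	ambiguous	-> * ->	predicted
SCO5536	scr5536	Panek2008	ambiguous	<- * ->	termed #234
SCO5537	scr5537	Swiercz2008	ambiguous	-> * <-	predicted
SCO5757	scr5756	Swiercz2008	ambiguous	-> * ->	predicted
SCO6277	scr6277	Moody2013	cis_asRNA	-> <= ->	mRNA up-regulated in rnc mutant
SCO6283	scr6284	Moody2013	ambiguous	-> * ->	predicted
SCO6284	scr6284	Moody2013	ambiguous	-> * ->	predicted
SCO6284	scr6285	Moody2013	ambiguous	-> <= ->	predicted
SCO6396	scr6396	Moody2013	ambiguous	-> * ->	predicted
SCO6716	scr6716	Moody2013	cutoRNA	-> <= <-	mRNA up-regulated in rnc mutant
SCO6716	scr6717	Moody2013	cutoRNA	-> => <-	-
SCO6728	scr6729	Moody2013	cutoRNA	-> => <-	mRNA up-regulated in rnc mutant
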