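# Curated S. coelicolor antisense-detection panel: 30 genes tested for a
# cognate antisense transcript by 5'/3' RACE and northern blot.
# set: experimental = mRNA co-precipitated with RNase III in vivo (BARD);
#      control = in-vitro RNase III targets and sigma-factor genes.
# bard_ratio: enrichment ratio in the RNase III co-IP (BARD);
# fold_rnc: fold change of the mRNA in the rnc deletion mutant vs wild type;
# race_5prime/race_3prime/northern: detection result, + or -;
# race_strain: strain(s) the final RACE data came from;
# rnaseq_5prime: independent confirmation in two RNA-seq datasets.
gene_id	set	product	rnase3_relation	bard_ratio	fold_rnc	race_5prime	race_3prime	race_strain	northern	rnaseq_5prime
SCO0168	experimental	Possible regulatory protein	coIP	100	2.41	+	-	WT	-	+/+
SCO0198	experimental	Hypothetical protein	coIP	47.6	2.70	+	+	WT	+	-/-
SCO0219	experimental	Putative nitrate reductase delta chain	coIP	30	2.18	+	+	WT,RNC	+	-/-
SCO0323	experimental	Hypothetical protein	coIP	138	1.62	+	+	WT,RNC	+	+/+
SCO0494	experimental	Probable iron-siderophore binding lipoprotein	coIP	19	-2.14	+	+	RNC	+	-/-
SCO0703	experimental	Putative regulatory protein	coIP	119	1.36	+	+	RNC	+	-/-
SCO0772	experimental	Putative regulatory protein	coIP	3	2.46	+	+	WT,RNC	+	+/-
SCO0864	experimental	Probable ECF-family sigma factor	coIP	234	1.70	+	+	WT	+	-/-
SCO1626	experimental	Cytochrome P450	coIP	22.8	-2.6	+	+	WT,RNC	+	+/+
SCO2081	experimental	Hypothetical protein	coIP	86	1.23	+	+	WT,RNC	-	-/-
SCO2198	experimental	Glutamine synthetase I	coIP	12.4	2.9	+	+	RNC	+	+/+
SCO3983	experimental	Hypothetical protein	coIP	1.5	2.14	+	+	WT,RNC	+	+/-
SCO4077	experimental	Hypothetical protein	coIP	184	-1.01	+	+	WT,RNC	+	+/-
SCO4878	experimental	Glycosyltransferase	coIP	1.6	2.00	+	+	RNC	-	+/-
SCO5040	experimental	Hypothetical protein	coIP	122	1.22	+	+	RNC	-	-/-
SCO5112	experimental	Putative ABC transport system integral membrane protein BldKA	coIP	1.4	2.56	+	+	WT,RNC	+	+/-
SCO5123	experimental	Small membrane protein	coIP	247	1.24	+	+	WT,RNC	+	+/-
SCO2792	control	AdpA	in_vitro_binding			+	+	RNC	+	+/+
SCO5572	control	RNase III	in_vitro_binding			+	+	WT	+	+/+
SCO5737	control	Guanosine pentaphosphate synthetase/polyribonucleotide nucleotidyltransferase	in_vitro_binding			-	-	-	-	+/+
SCO0600	control	RNA polymerase sigma factor SigB	unknown			+	+	WT	+	+/-
SCO0895	control	RNA polymerase sigma factor HrdC	unknown			-	-	-	-	+/-
SCO2465	control	RNA polymerase sigma factor HrdA	unknown			-	-	-	-	+/+
SCO3202	control	RNA polymerase sigma factor HrdD	unknown			-	-	-	-	+/+
SCO3356	control	RNA polymerase sigma factor SigE	unknown			-	-	-	-	+/-
SCO4769	control	RNA polymerase sigma factor SigD	unknown			-	-	-	-	+/-
SCO5216	control	RNA polymerase sigma factor SigR	unknown			+	+	WT	+	+/-
SCO5243	control	RNA polymerase sigma factor SigH	unknown			+	+	WT	+	+/+
SCO5621	control	RNA polymerase sigma factor WhiG	unknown			-	-	-	-	-/-
SCO5820	control	RNA polymerase sigma factor HrdB	unknown			-	-	-	-	+/-
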