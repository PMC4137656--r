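locus_a	locus_b	product	identity	len_b	len_a	snp_count	nonsyn_snp_count	omega	notes
WD_0294	WREC_0283	ankyrin repeat domain protein	89.4	1815	1626	4	4	NA	189 bp insertion
WD_0443	WREC_0442	OTU-like cysteine protease	97.1	927	906	7	6	1.59	21 bp insertion
WD_0550	WREC_0541	ankyrin repeat domain protein	87.4	789	990	2	2	NA	99 bp deletion, C-terminal frameshift, alternate start/stop sites
WD_0722	WREC_0649	hypothetical protein	92.0	462	450	25	21	4.25	9 bp insertion, 3 bp insertion
WD_0996	WREC_0956	transposase	89.1	744	801	1	0	0	alternate start site, transposase insertion
WD_1007	WREC_0973	hypothetical protein	95.1	366	351	3	2	0.42	15 bp insertion
WD_1039	WREC_1007	collagen triple helix repeat protein	97.5	405	1425	1	1	NA	9 bp insertion, scaffold break
WD_1063	WREC_1036	Wsp surface antigen	97.9	708	714	9	8	2.55	6 bp deletion
WD_1278	WREC_1268	hypothetical protein	92.1	2604	2766	56	51	6.07	162 bp deletion
WD_1298	WREC_1289	RpoD	97.2	1974	1929	10	6	0.39	18 bp insertion, 27 bp insertion
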