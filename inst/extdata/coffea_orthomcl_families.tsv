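family	C_arabica	C_canephora	V_vinifera	S_lycopersicum	G_max	R_communis	O_sativa	A_thaliana	annotation
1	446	189	1402	808	2532	1378	813	847	Serine-threonine kinase
2	152	51	580	212	967	461	478	447	PPR repeat protein
6	84	41	193	123	226	99	101	108	Cytochrome P450
544	21	6	1	-	-	-	-	-	Cystatin
453	14	4	1	7	3	1	1	1	NBS LRR resistance protein
1231	13	5	-	-	-	-	-	-	Small secreted glycine-rich protein
4031	10	-	-	-	-	-	-	-	Glycine-rich protein
1510	7	1	1	-	2	1	1	3	UDP-glucosyltransferase
2703	6	3	-	1	1	-	1	-	Cysteine proteinase inhibitor like protein
3289	6	-	1	-	2	-	2	-	NBS LRR resistance protein
5056	6	1	-	1	-	-	-	-	Alcohol dehydrogenase
2306	5	1	-	2	1	1	2	-	Cytochrome P450
2722	5	1	-	1	1	2	1	1	NBS LRR resistance protein
3294	5	-	1	-	3	-	1	1	Poly-A binding protein
3303	5	1	2	1	-	-	-	1	NADPH-dependent cinnamyl alcohol dehydrogenase
3305	5	2	1	2	-	-	-	-	Specific tissue protein 2
4049	5	2	1	1	-	-	1	-	Sugar transport protein
4070	5	-	1	1	3	-	-	-	Cytochrome P450
7241	5	1	1	-	-	-	1	-	Potato type II serine proteinase inhibitor family
10956	5	-	-	-	-	-	-	-	Hypothetical protein
7610	4	1	-	1	-	-	-	1	Ubiquitin-conjugating enzyme
7611	4	1	-	1	1	-	-	-	P-glycoprotein ABC
7613	4	-	-	2	1	-	-	-	Hexose transporter
9014	4	1	-	-	-	1	-	-	GH3 family protein/Indole-3-acetic acid-amido synthetase
10273	4	1	-	-	-	-	-	-	Potato type II serine proteinase inhibitor family
11588	4	-	-	-	-	-	-	-	Small secreted glycine-rich protein
11617	4	-	-	-	-	-	-	-	Hypothetical protein
12384	4	-	-	-	-	-	-	-	Hypothetical protein
12385	4	-	-	-	-	-	-	-	Defensin/gamma thionin
12386	4	-	-	-	-	-	-	-	Hypothetical protein
7324	3	2	-	-	2	-	-	-	Helix-loop-helix DNA-binding protein
9019	3	-	-	1	-	1	-	-	Zinc/iron transporter
9830	3	-	3	-	-	-	-	-	Eukaryotic initiation factor (eIF1)/SU1
10271	3	1	-	-	-	-	1	-	Metallothionein
10276	3	-	-	-	-	1	-	1	SEC14 cytosolic factor family protein
10293	3	-	-	1	1	-	-	-	ABC transporter
10300	3	1	-	-	1	-	-	-	Phytochrome B/histidine kinase
10309	3	1	-	1	-	-	-	-	Oxidoreductase
11058	3	-	1	1	-	-	-	-	ATP-binding cassette transporter
11594	3	-	-	-	-	-	-	1	*A. thaliana*-related cystatin
11600	3	-	-	-	-	-	1	-	Alcohol dehydrogenase
11607	3	1	-	-	-	-	-	-	CAAX amino-terminal protease
11626	3	1	-	-	-	-	-	-	Hypothetical protein
13353	3	-	-	-	-	-	-	-	Hypothetical protein
13392	3	-	-	-	-	-	-	-	GDP-D-mannose 4,6-dehydratase
14410	3	-	-	-	-	-	-	-	No hits found
14413	3	-	-	-	-	-	-	-	No hits found
14414	3	-	-	-	-	-	-	-	Aspartate aminotransferase superfamily protein
14418	3	-	-	-	-	-	-	-	HAT transposase element
14420	3	-	-	-	-	-	-	-	Protein translation factor SUI1
8498	2	5	-	-	-	-	-		Rapid Alkalinization Factor (RALF)-like protein
9023	2	3	-	-	-	1	-	-	GTP binding protein
10281	2	3	-	-	-	-	-	-	No hits found
12371	2	2	-	-	-	-	-		Hydroxyproline-rich glycoprotein/extension
12375	2	2	-		-	-	-	-	No hits found
1715	-	4	1	2	1	8	-	-	Viroid polyprotein ORF4 protein
6375	-	4	2	1	1	-	-	-	NBS LRR resistance protein
9679	-	3	1	-	1	1	-	-	Replication factor A 1
10952	-	3	1	-	-	1	-	-	LTR retrotransposon
11055	-	5	-	-	-	-	-	-	Small glycine-rich protein
14392	-	3	-	-	-	-	-	-	Kelch repeat-containing phosphatase
14397	-	3	-	-	-	-	-	-	Albumin/sulfur-rich seed storage protein
14809	-	3	-	-	-	-	-	-	Hypothetical protein
14813	-	3	-	-	-	-	-	-	Miraculin-like protein
14814	-	3	-	-	-	-	-	-	Invertase inhibitor
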