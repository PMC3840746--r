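# Curated panel of 463F/463R primer-site variants observed in published 16S
# rRNA records of aerobic endospore-forming bacilli and relatives, keyed by
# NCBI accession.  fwd_site / rev_site are sense-strand annealing-site
# sequences (forward site = forward oligo orientation; reverse site = the
# segment the reverse oligo anneals to, containing the HaeIII GGCC in intact
# records).  pct_similarity is the reported integer % similarity of the
# marker region to the Bacillus subtilis-type reference; site is the
# reported HaeIII-site flag; span_start/span_end the reported 1-based marker
# span in the 16S gene.
taxon	accession	fwd_site	rev_site	pct_similarity	site	span_start	span_end
Alicyclobacillus sacchari	AB264020	CTGAAACTCAAAGGAATTGACG	AATCCGTTCCCGGGCCTT	88	+	913	1374
Alicyclobacillus vulcanalis	AY425985	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	88	+	894	1355
Alicyclobacillus tolerans	Z21979	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	87	-	906	1365
Amphibacillus sediminis	AB243866	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGTCTT	96	-	928	1386
Amphibacillus fermentum	AF418603	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGTCTT	93	-	910	1368
Aneurinibacillus aneurinilyticus	X94194	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGTCTT	91	-	903	1369
Brevibacillus centrosporus	D78458	GTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	91	+	917	1377
Brevibacillus brevis	AB271756	GTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	91	+	896	1356
Brevibacillus invocatus	AF378232	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	91	+	896	1356
Gracilibacillus lacisalsi	DQ664540	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGCCTT	94	+	933	1393
Gracilibacillus dipsosauri	AB101591	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGCCTT	95	+	923	1383
Paenibacillus polymyxa	D16276	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGTCTT	90	-	913	1375
Virgibacillus pantothenticus	D16275	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGTCTT	95	-	919	1375
Virgibacillus salexigens	Y11603	CTGAAACTCAAAAGAATTNACG	AATACGTTCCCGGGCCTT	95	+	921	1379
Virgibacillus marismortui	AJ009793	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGCCTT	95	+	947	1407
Virgibacillus koreensis	AY616012	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGCCTT	97	+	926	1386
Virgibacillus dokdonensis	AY822043	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGTCTT	96	-	927	1383
Virgibacillus subterraneus	FJ746573	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGCCCTT	91	+	905	1362
Geobacillus stearothermophilus	AB021196	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	93	+	912	1376
Geobacillus debilis	AJ564616	CTGAAACTCAAAGGAATTGACG	AATACGTTCTCGGGCCTT	91	-	936	1398
Geobacillus tepidamans	AY563003	GTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	95	+	872	1334
Filobacillus milosensis	AJ238042	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	94	+	915	1375
Jeotgalibacillus alimentarius	AF281158	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	96	+	911	1373
Ureibacillus thermosphaericus	AB101594	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	92	+	931	1392
Lysinibacillus sphaericus	AJ310084	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	93	+	920	1382
Terribacillus saccharophilus	AB243845	CTGAAACTCAAAAGAATTGACG	AATACGTTCCCGGGCCTT	94	+	922	1382
Bacillus marisflavi	AF483624	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	100	+	909	1371
Bacillus aquimaris	AF483625	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	99	+	910	1372
Bacillus subtilis subsp. subtilis	AJ276351	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	95	+	919	1379
Bacillus pseudomycoides	AF013121	CTGAAACTCAAAGGATTTGACG	AATACGTTCCCGGGCCTT	95	+	932	1392
Bacillus ginsengihumi	AB245378	TTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	98	-	914	1376
Bacillus endophyticus	AF295302	CTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGTCTT	96	-	906	1362
Bacillus arsenicus	AJ606700	TTGAAACTCAAAGGAATTGACG	AATACGTTCCCGGGCCTT	94	-	928	1390
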