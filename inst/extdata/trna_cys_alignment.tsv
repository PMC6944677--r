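# Block-structured alignment of the mitochondrial tRNA-Cys (MT-TC) gene
# from 17 vertebrate species (in-paper alignment, transcribed). Blocks are
# anchored at canonical tRNA positions 1, 8, 10, (d-loop), 22, 26, 27, 32,
# 39, 44, 49, (t-loop), 61, 66, 73. Position 30 = 4th column of
# anticodon_stem_5p, the site of the m.5802A>G mutation in gene orientation.
species	acceptor_stem_5p	connector	d_stem_5p	d_loop	d_stem_3p	position_26	anticodon_stem_5p	anticodon_loop	anticodon_stem_3p	variable_region	t_stem_5p	t_loop	t_stem_3p	acceptor_stem_3p	discriminator
Cebus albifrons	AGCCCTG	AG	GTGA	ACTG	TCAT	G	TTGAA	CTGCAAA	TTCAA	AGAA	GCAGC	TTCAAT	GCTGC	CGGGGCT	T
Cercopithecus aethiops	AGCCCCG	AG	GTGA	TTT	TCAT	G	TTAAA	TTGCAAG	TTTAA	AGGA	GCAGT	TTTGAGTT	TCTGC	CGGGGCT	T
Colobus guereza	AGTCCCG	AG	GTGA	TTT	TCAT	G	TTGAA	TTGCAAA	TTCAA	AGGA	GCAGC	TTAAGACC	TCTGC	CGGGGCT	T
Gorilla gorilla	AGCTCCG	AG	GTGA	ATT	TCAT	A	TTGAA	TTGCAAA	TTCGA	AGAA	GCAGC	TTCAAA	CCTGC	CGGGGCT	T
Homo sapiens	AGCTCCG	AG	GTGA	TTT	TCAT	A	TTGAA	TTGCAAA	TTCGA	AGAA	GCAGC	TTCAAA	CCTGC	CGGGGCT	T
Hylobates lar	AGTCCCG	AA	GTGG	TTT	TCAC	G	TTGAA	TTGCAAA	TTCAA	AGGA	GCAGC	TTCAAT	CCTGC	CGGGGCT	T
Lemur catta	AGCCCTG	TA	GTGA	ATA	TCAC	G	TTGGA	TTGCAAA	TTCAA	AGAA	GCAGC	TTCAAT	TCTGC	CGGGGCT	T
Macaca mulatta	AGCCCCG	AG	GTGA	TTT	TCAT	G	TTGAA	TTGCAAG	TTCAA	AGGA	GCAGT	CTTAGAGTT	TCTGC	CGGGGCT	T
Macaca sylvanus	AGCTCCG	AG	GTGA	TTT	TCAT	G	TTGAA	TTGCAAA	TTCAA	AGGA	GCAGT	TCCAAAGTT	TCTGC	CGGGGCT	T
Nycticebus coucang	GGCCTCG	AG	GTGA	TAAA	TCAT	A	TTGAA	TTGCAAA	TTCAA	AGGA	GCAGC	TTCAAT	TCTGC	CGGGGCT	T
Pan paniscus	AGCTCTG	AG	GTGA	TTT	TCAT	A	TTGAA	TTGCAAA	TTCAA	AGAA	GCAGC	TTCAAA	CCTGC	CGGGGCT	T
Pan troglodytes	AGCTCTG	AG	GTGA	TTT	TCAT	A	TTGAA	TTGCAAA	TTCGA	AGAA	GCAGC	TTCAAA	CCTGC	CGGGGCT	T
Papio hamadryas	AGCCCCG	AG	GTGA	TTT	TCAC	A	TTGAA	TTGCAAG	TTCGA	AGGA	GCAGC	TTTAAGTT	TCTGC	CGGGGCT	T
Pongo pygmaeus	AGCCCTG	AG	GTGA	TTG	TCAT	G	TTGAA	TTGCAAA	TTCGA	AGGA	GCAGC	TTTAAGG	CCTGC	CGGGGCT	T
Pongo pygmaeus abelii	AGCCCCG	AG	GTGA	TTG	TCAT	G	TTGAA	TTGCAAA	TTCGA	AGGA	GCAGC	TTTAAGG	CCTGC	CGGGGCT	T
Tarsius bancanus	AGTCCTG	AA	GTGA	ATA	TCAT	A	TTGAA	TTGCAAA	TTCAA	AGAA	GCAGC	TTCAAT	TCTGC	CGGGACT	T
Trachypithecus obscurus	AGCCCCG	AG	GTGG	TTT	TCAT	G	TTGAA	TTGCAAA	TTCAA	AGGA	GCAGT	TAGATT	TCTGC	CGGGGCT	T
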