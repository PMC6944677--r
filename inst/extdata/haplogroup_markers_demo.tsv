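# DEMO haplogroup marker database — illustrative only, not a phylogenetic
# reference. D4 markers are well-known D4/D/M-lineage positions; the other
# entries exist to exercise partial-overlap ranking.
haplogroup	position	ref	alt
D4	3010	G	A
D4	4883	C	T
D4	5178	C	T
D4	8414	C	T
D4	10400	C	T
D4	14668	C	T
D4	14783	T	C
D4	15043	G	A
D4	16362	T	C
D5-demo	5178	C	T
D5-demo	1107	T	C
D5-demo	10397	A	G
B4-demo	499	G	A
B4-demo	16189	T	C
B4-demo	16217	T	C
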