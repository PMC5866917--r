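gene_id	residue	ref_aa	k
GENE01	100	R	12
GENE02	55	E	8
GENE03	210	R	20
GENE04	77	G	6
GENE05	140	R	7
GENE06	33	E	9
GENE07	61	E	11
GENE08	99	K	6
GENE09	12	R	15
GENE10	305	A	6
GENE11	47	S	5
GENE12	88	R	10
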