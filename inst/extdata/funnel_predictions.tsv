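gene	residue	alt_aa	label
GENE01	100	K	probably_damaging
GENE02	55	Q	possibly_damaging
GENE03	210	W	probably_damaging
GENE04	77	A	benign
GENE04	77	S	benign
GENE05	140	T	benign
GENE07	61	K	probably_damaging
GENE08	99	E	possibly_damaging
GENE09	12	V	probably_damaging
GENE10	305	L	benign
GENE10	305	M	probably_damaging
GENE11	47	F	possibly_damaging
GENE12	88	Y	probably_damaging
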