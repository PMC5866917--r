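gene	residue	max_freq	source
GENE01	100	0.02	dbSNP
GENE01	100	0.004	Kaviar
GENE02	55	0.05	1000G
GENE03	210	0.30	ExAC
GENE07	61	0.01	dbSNP
GENE99	5	0.50	dbSNP
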