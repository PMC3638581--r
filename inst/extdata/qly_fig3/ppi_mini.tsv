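# Miniature undirected interaction network over the worked-example genes
# (synthetic stand-in shaped around the published gene names).
TNF	TNFRSF1A
TNFRSF1A	RAF1
RAF1	NFKB2
IL1B	IL1R1
IL1R1	AKT1
AKT1	SRC
SRC	PTK2
PTK2	NFKB1
NFKB1	NFKB2
NFKB1	RELA
NFKB2	RELB
RELA	RELB
VEGFA	KDR
KDR	SRC
NFKB1	PTGS2
PTGS1	PTGS2
CASP1	NFKB1
PPARG	NFKB1
AHR	PPARG
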