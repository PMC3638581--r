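GO:0006954	Inflammatory response|inflammatory response	IL1B	IL1R1	TNF	TNFRSF1A	NFKB1	RELA	PTGS2	CASP1
GO:0045765	Angiogenesis|regulation of angiogenesis	VEGFA	KDR	SRC	RAF1	PTK2
GO:0006955	Immune response|immune response	TNF	IL1B	CASP1	PPARG	NFKB2	RELB
GO:0051092	NF-kB activity|positive regulation of NF-kB transcription factor activity	NFKB1	NFKB2	RELA	RELB	AKT1	PTK2
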