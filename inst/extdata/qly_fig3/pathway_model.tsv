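# RA-specific signaling model for the QLY worked example.
# Directed edges: source <TAB> target <TAB> pathway label.
# Pathway membership of a node = labels of its OUTGOING edges; nodes with
# only incoming edges of a label are outputs regulated by that pathway.
# The NFKB1-NFKB2-RELA-RELB transcription-factor complex is declared as a
# feedback loop; PTGS2 is the designated downstream effector (sink).
@loop	NFKB1	NFKB2	RELA	RELB
@sink	PTGS2
IL1B	IL1R1	IL1B
IL1R1	AKT1	IL1B
AKT1	SRC	IL1B
SRC	PTK2	IL1B
PTK2	NFKB1	NFKB
NFKB1	PTGS2	NFKB
RELA	PTGS2	NFKB
RELB	PTGS2	NFKB
VEGFA	KDR	VEGFA
KDR	SRC	VEGFA
TNF	TNFRSF1A	TNF
TNFRSF1A	RAF1	TNF
RAF1	NFKB2	TNF
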