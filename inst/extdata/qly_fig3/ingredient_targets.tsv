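ingredient	herb	gene
Matrine	Ku-Shen	IL1R1
Kurarinone	Ku-Shen	AKT1
Kurarinone	Ku-Shen	PTK2
Kurarinone	Ku-Shen	NFKB1
Sinomenine	Qing-Feng-Teng	NFKB1
Sinomenine	Qing-Feng-Teng	SRC
Berberine	Huang-Bai	KDR
Diosgenin	Bi-Xie	NFKB2
Diosgenin	Bi-Xie	RAF1
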