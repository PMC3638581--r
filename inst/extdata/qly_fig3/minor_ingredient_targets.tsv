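ingredient	herb	gene
Xanthohumol	Ku-Shen	PTGS1
Xanthohumol	Ku-Shen	AHR
Kuraridin	Ku-Shen	AHR
Sophoraflavanone	Ku-Shen	AHR
Salicylaldehyde	Qing-Feng-Teng	AHR
Allantoin	Qing-Feng-Teng	AHR
beta-Elemene	Huang-Bai	AHR
Ferulic acid	Huang-Bai	PTGS1
cis-Limonene oxide	Huang-Bai	PTGS1
Phellochinin A	Huang-Bai	PTGS1
Piperitol	Bi-Xie	AHR
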