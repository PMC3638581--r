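# RA genes, computationally predicted (synthetic selection)
SRC
AKT1
CASP1
PPARG
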