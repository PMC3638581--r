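# RA genes, known (OMIM-like provenance; synthetic selection)
TNF
IL1B
HTR3A
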