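name	protospacer	note
ISG15	GTTCGCTGCCTCTCAGCCGC	targets the ISG15 promoter CGI
scrambled	GAACAGTCGCGTTTGCGACT	control guide with minimal genomic similarity
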