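# Default transposon taxonomy.
# One "code<TAB>name" per line; codes are slash-separated integer paths.
1	Retrotransposon
1/1	LTR
1/1/1	Copia
1/1/2	Gypsy
1/1/3	ERV
1/1/4	BelPao
1/2	non-LTR
1/2/1	LINE
1/2/2	SINE
2	DNA transposon
2/1	TIR
2/1/1	Tc1-Mariner
2/1/2	hAT
2/1/3	CMC
2/1/4	Sola
2/1/5	Zator
2/1/6	Novosib
2/2	Helitron
2/3	MITE
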