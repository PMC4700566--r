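chrom	start	end	block
Chr1	0	1800000	A
Chr2	0	1800000	B
Chr3	0	1800000	C
Chr4	0	1800000	D
Chr5	0	1800000	E
Chr1	2000000	3800000	F
Chr2	2000000	3800000	G
Chr3	2000000	3800000	H
Chr4	2000000	3800000	I
Chr5	2000000	3800000	J
Chr1	4000000	5800000	K
Chr2	4000000	5800000	L
Chr3	4000000	5800000	M
Chr4	4000000	5800000	N
Chr5	4000000	5800000	O
Chr1	6000000	7800000	P
Chr2	6000000	7800000	Q
Chr3	6000000	7800000	R
Chr4	6000000	7800000	S
Chr5	6000000	7800000	T
Chr1	8000000	9800000	U
Chr2	8000000	9800000	V
Chr3	8000000	9800000	W
Chr4	8000000	9800000	X
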