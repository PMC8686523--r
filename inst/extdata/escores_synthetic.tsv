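kmer	escore
TTTTCGGA	0.47
TTCGGATT	0.45
ATTCGGAT	0.42
GACAGTCA	0.44
AGACAGTC	0.41
ACTGACAG	0.38
ACTGTCTT	0.35
CAGGTACC	0.33
ACAGGTAC	0.31
TTCGGAAA	0.29
AAGACAGT	0.27
GGTACCTT	0.24
AAAAAAAA	0.12
ACGTACGT	0.08
CCCCGGGG	0.05
GATCGATC	-0.02
TTAACCGG	-0.11
CGCGCGCG	-0.19
ATATATAT	-0.25
GGCCGGCC	-0.33
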