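MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF motifA
letter-probability matrix: alength= 4 w= 7
0.033333 0.033333 0.033333 0.900000
0.033333 0.033333 0.033333 0.900000
0.033333 0.900000 0.033333 0.033333
0.033333 0.033333 0.900000 0.033333
0.033333 0.033333 0.900000 0.033333
0.900000 0.033333 0.033333 0.033333
0.033333 0.033333 0.033333 0.900000

MOTIF motifB
letter-probability matrix: alength= 4 w= 7
0.033333 0.033333 0.900000 0.033333
0.900000 0.033333 0.033333 0.033333
0.033333 0.900000 0.033333 0.033333
0.900000 0.033333 0.033333 0.033333
0.033333 0.033333 0.900000 0.033333
0.033333 0.033333 0.033333 0.900000
0.033333 0.900000 0.033333 0.033333

MOTIF motifC
letter-probability matrix: alength= 4 w= 8
0.900000 0.033333 0.033333 0.033333
0.033333 0.900000 0.033333 0.033333
0.033333 0.033333 0.033333 0.900000
0.033333 0.033333 0.900000 0.033333
0.600000 0.200000 0.100000 0.100000
0.033333 0.900000 0.033333 0.033333
0.900000 0.033333 0.033333 0.033333
0.100000 0.100000 0.200000 0.600000

MOTIF motifD
letter-probability matrix: alength= 4 w= 10
0.400000 0.200000 0.200000 0.200000
0.100000 0.700000 0.100000 0.100000
0.250000 0.250000 0.250000 0.250000
0.033333 0.033333 0.900000 0.033333
0.033333 0.033333 0.900000 0.033333
0.600000 0.150000 0.150000 0.100000
0.100000 0.100000 0.100000 0.700000
0.250000 0.250000 0.250000 0.250000
0.100000 0.700000 0.100000 0.100000
0.400000 0.200000 0.200000 0.200000
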