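>GGQCYR401C2J7Z_1
ATATTGGAACAATATATCTAATACTAGGATCCTGATCAGCTTTTATAGGGACTGCTTTTAGTATCCTGAT
CCGTATAGAACTAGGCCAACCTGGGACCCTGATTGGAAATGATCAAATCTACAATGTTATGGTGACTGCT
CATGCTTTTTGTAATAATTTTCTTTATAGTTATACCAATTATGATTGGAGGGTTTGGGAATTGATTAGTC
CCCCTAATAATTGGGGCTCCTGATATAGCCTTCCCACGTATAAATAATATAAGTTTCTGATTACTCCCCC
CTTCCCTTACCTTATTAGTCGCGGGAGGTTTAGTAGAAAGAGCGGCAGGAACAGGA
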