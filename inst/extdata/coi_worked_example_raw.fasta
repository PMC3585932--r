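>GGQCYR401C2J7Z length = 354 xy = 1142_0845 region = 1
TTTCAACAAATCATAAGGATATTGGAACAATATATCTAATACTAGGATCCTGATCAGCTTTTATAGGGAC
TGCTTTTAGTATCCTGATCCGTATAGAACTAGGCCAACCTGGGACCCTGATTGGAAATGATCAAATCTAC
AATGTTATGGTGACTGCTCATGCTTTTTGTAATAATTTTCTTTATAGTTATACCAATTATGATTGGAGGG
TTTGGGAATTGATTAGTCCCCCTAATAATTGGGGCTCCTGATATAGCCTTCCCACGTATAAATAATATAA
GTTTCTGATTACTCCCCCCTTCCCTTACCTTATTAGTCGCGGGAGGTTTAGTAGAAAGAGCGGCAGGAAC
AGGA
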