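>ColFol-for modified Folmer LCO1490, degenerate 3' codons
TTTCAACAAATCATAARGAYATYGG
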