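>AP1_synthetic synthetic AP-1-like (TGA[CG]TCA) count matrix, built in code, not from a motif database
A [   2   2 194   2   2   2 194 ]
C [   2   2   2  97   2 194   2 ]
G [   2 194   2  97   2   2   2 ]
T [ 194   2   2   2 194   2   2 ]
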