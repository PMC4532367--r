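> SYN_HRE.1 synthetic hypoxia-response-element-like motif (extended TRCGTGC consensus around the RCGTG core); constructed stand-in, not a database matrix
A [ 4  1 10  0  0  0  0  1 ]
C [ 4  1  0 20  0  0  0 17 ]
G [ 8  1 10  0 20  0 20  1 ]
T [ 4 17  0  0  0 20  0  1 ]
> SYN_AP1.1 synthetic AP-1/TRE-like motif (TGACTCA); constructed stand-in, not a database matrix
 0  1 18  1  0  1 17
 1  0  0 17  0 18  1
 0 18  1  1  0  1  1
19  1  1  1 20  0  1
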