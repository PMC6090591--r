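>FKH_synthetic forkhead-like (synthetic counts, not a JASPAR record)
A  [ 2 38 37  1  0 36 ]
C  [ 3  0  1  0  1  2 ]
G  [ 1  1  1  0  0  1 ]
T  [ 34  1  1 39 39  1 ]
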