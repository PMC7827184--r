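
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -1  -2  -3  -4  -2  -1  -2  -3  -2   1   2  -2   8   0  -3  -2  -1  -2  -1   1    0   0   0   0   0   0   0   0   0   4   8   0  83   0   0   0   0   0   0   4  1.62     0.03
    2 K    -1   2   0  -1  -4   1   1  -2  -1  -3  -3   5  -2  -4  -1   0  -1  -4  -2  -3    0   9   4   0   0   5   9   0   0   0   0  64   0   0   0   4   0   0   0   0  0.83     0.05
    3 V     0  -3  -3  -4  -1  -3  -3  -4  -4   3   1  -3   1  -1  -3  -2   0  -3  -1   5    4   0   0   0   0   0   0   0   0  16   8   0   4   0   0   0   4   0   0  62  0.91     0.05
    4 A     5  -2  -2  -2  -1  -1  -1   0  -2  -2  -2  -1  -1  -3  -1   1   0  -3  -2  -1   77   0   0   0   0   4   4   4   0   0   0   4   0   0   0   7   0   0   0   0  0.74     0.04
    5 D    -2  -2   1   6  -4   0   2  -2  -1  -4  -4  -1  -3  -4  -2   0  -1  -5  -3  -4    0   0   4  70   0   4  12   0   0   0   0   4   0   0   0   4   0   0   0   0  1.05     0.06

                      K         Lambda
Standard Ungapped    0.1337     0.3176
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1337     0.3176
PSI Gapped           0.0410     0.2670
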