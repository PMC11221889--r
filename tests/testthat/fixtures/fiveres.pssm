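
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M     -1  -2  -3  -4  -5   0   1   2   3   4   5  -1   8   0  -2  -1   0  -3  -1   1    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  0.75 0.12
    2 K     -1   2   0  -1  -3   1   1  -2  -1  -3  -2   5  -1  -3  -1   0  -1  -3  -2  -2    0   5   0   0   0   5   5   0   0   0   0  85   0   0   0   0   0   0   0   0  0.60 0.10
    3 T      0  -1   0  -1  -1  -1  -1  -2  -2  -1  -1  -1  -1  -2  -1   1   5  -2  -2   0    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  10  90   0   0   0  0.55 0.09
    4 A      4  -1  -2  -2   0  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0  -3  -2   0   90   0   0   0   0   0   0   0   0   0   0   0   0   0   0  10   0   0   0   0  0.50 0.08
    5 Y     -2  -2  -2  -3  -2  -1  -2  -3   2  -1  -1  -2  -1   3  -3  -2  -2   2   7  -1    0   0   0   0   0   0   0   0   5   0   0   0   0   5   0   0   0   0  90   0  0.70 0.11

                      K         Lambda
Standard Ungapped     0.1347    0.3179
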