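
Last position-specific scoring matrix computed, weighted observed percentages rounded down (synthetic toy fixture)
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 A     4  -1  -2  -2   0  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0  -3  -2   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    2 K    -1   2   0  -1  -3   1   1  -2  -1  -3  -2   5  -1  -3  -1   0  -1  -3  -2  -2   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    3 T     0  -1   0  -1  -1  -1  -1  -2  -2  -1  -1  -1  -1  -2  -1   1  -2  -2  -2   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
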