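>SYN_GCRICH synthetic GC-rich factor
A [  1  1  1  1  1  1  1  1  1 ]
C [  1 17 17  1 17  1  1 17  1 ]
G [ 17  1  1 17  1 17 17  1 17 ]
T [  1  1  1  1  1  1  1  1  1 ]
>SYN_MIXED synthetic mixed-composition factor
A [  1 17  1  1  1  1 17  1  1 ]
C [  1  1 17  1  1 17  1  1  1 ]
G [ 17  1  1 17  1  1  1  1 17 ]
T [  1  1  1  1 17  1  1 17  1 ]
>SYN_TATA synthetic TATA-box-like factor
16 1 15 1 14 15 1 15
1 1 1 1 2 1 1 1
1 1 1 1 2 1 1 1
2 17 3 18 2 3 18 3
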