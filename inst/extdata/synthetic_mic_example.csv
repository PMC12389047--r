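mic,frequency
0.5,0.02
1,0.07
2,0.18
4,0.30
8,0.22
16,0.12
32,0.05
64,0.03
128,0.01
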