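item,a,d
1,1,0.96
2,1,0.67
3,1,0.67
4,1,0.28
5,1.43,0.11
6,0.69,-0.04
7,1.7,-0.87
8,1.48,-0.65
9,1,-0.25
10,1,0.09
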