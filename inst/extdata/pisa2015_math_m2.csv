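item,a,d
1,0.62,-0.09
2,1,0.02
3,1,0.61
4,0.59,0.91
5,1.78,-0.91
6,2.3,-1.8
7,0.76,-0.25
8,1,-0.03
9,0.63,0.03
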