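item,group,a,d
1,A,1,0.96
1,B,1.2,0.5
2,NA,1,0.67
3,NA,1,0.67
4,NA,1,0.28
5,NA,1.43,0.11
6,NA,0.69,-0.04
7,NA,1.7,-0.87
8,NA,1.48,-0.65
9,NA,1,-0.25
10,NA,1,0.09
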