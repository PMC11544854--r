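score,count
0,0
1,0
2,1
3,3
4,5
5,2
6,1
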