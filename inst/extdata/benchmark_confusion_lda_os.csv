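computer_score,1,2,3,4,5,6,7,8,9
1,113,26,13,1,4,1,3,1,0
2,10,70,47,12,0,0,0,0,0
3,0,23,55,31,18,10,0,0,0
4,1,9,38,41,12,12,5,1,0
5,0,0,3,17,11,9,3,1,0
6,0,0,2,15,23,35,14,4,0
7,0,0,1,2,17,23,19,9,0
8,0,0,0,0,0,0,0,0,0
9,0,0,0,0,0,0,0,0,0
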