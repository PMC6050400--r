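computer_score,1,2,3,4,5,6,7,8,9
1,291,41,12,5,2,1,0,0,0
2,1,0,0,0,0,0,0,0,0
3,6,29,46,22,8,2,0,1,0
4,1,2,14,19,11,3,2,0,0
5,0,0,1,4,6,3,1,0,0
6,0,2,3,17,29,33,17,4,1
7,0,0,0,4,3,11,18,10,0
8,0,0,0,0,3,10,27,28,11
9,0,0,0,0,0,0,0,0,0
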