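computer_score,1,2,3,4,5,6,7,8,9
1,109,10,2,0,0,0,2,0,0
2,15,79,25,3,1,0,0,1,0
3,0,39,104,34,1,1,3,1,0
4,0,0,26,55,27,18,1,1,0
5,0,0,1,19,19,10,0,0,0
6,0,0,1,6,32,46,19,3,0
7,0,0,0,2,5,15,19,7,0
8,0,0,0,0,0,0,0,0,0
9,0,0,0,0,0,0,0,3,0
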