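computer_score,1,2,3,4,5,6,7,8,9
1,294,47,24,5,4,3,1,1,0
2,0,0,0,0,0,0,0,0,0
3,5,18,22,14,8,2,0,0,0
4,0,7,24,23,9,1,1,0,0
5,0,1,3,12,13,8,2,0,0
6,0,1,3,14,23,27,16,5,1
7,0,0,0,3,2,13,21,13,0
8,0,0,0,0,2,8,18,18,8
9,0,0,0,0,1,1,6,6,3
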