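i,j
1,2
2,3
3,4
4,5
5,6
6,7
7,8
8,9
9,10
10,11
11,12
12,13
13,14
14,15
15,16
16,17
17,18
18,19
2,18
3,17
4,16
5,14
6,12
7,11
8,10
13,19
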