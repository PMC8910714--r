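mode,eigenvalue
1,914248.1
2,71644.2
3,9452.9
4,6619.8
5,730.1
6,490.9
7,341.9
8,323.0
9,207.2
10,162.4
11,112.8
12,76.3
13,45.7
14,30.3
15,21.0
16,17.0
17,12.1
18,11.2
19,6.3
20,4.1
21,2.2
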