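length	count
4	6
5	6
6	14
7	18
8	18
9	19
10	10
11	25
12	12
13	16
14	13
15	15
16	6
17	3
18	10
19	4
20	3
21	2
22	3
25	2
26	1
30	1
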