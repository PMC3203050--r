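navbasis-layout 1
width: 20
height: 20
goal: 10 3
reward: 1
walls:
0 7 N
1 7 N
2 7 N
3 7 N
4 7 N
5 7 N
6 7 N
7 7 N
8 7 N
11 7 N
12 7 N
13 7 N
14 7 N
15 7 N
16 7 N
17 7 N
18 7 N
19 7 N
8 8 E
10 8 E
8 9 E
10 9 E
8 10 E
10 10 E
0 11 N
1 11 N
2 11 N
3 11 N
4 11 N
5 11 N
6 11 N
7 11 N
8 11 E
8 11 N
10 11 E
11 11 N
12 11 N
13 11 N
14 11 N
15 11 N
16 11 N
17 11 N
18 11 N
19 11 N
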