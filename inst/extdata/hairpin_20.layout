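navbasis-layout 1
width: 20
height: 20
goal: 19 0
reward: 1
walls:
1 0 E
5 0 E
9 0 E
13 0 E
17 0 E
1 1 E
3 1 E
5 1 E
7 1 E
9 1 E
11 1 E
13 1 E
15 1 E
17 1 E
1 2 E
3 2 E
5 2 E
7 2 E
9 2 E
11 2 E
13 2 E
15 2 E
17 2 E
1 3 E
3 3 E
5 3 E
7 3 E
9 3 E
11 3 E
13 3 E
15 3 E
17 3 E
1 4 E
3 4 E
5 4 E
7 4 E
9 4 E
11 4 E
13 4 E
15 4 E
17 4 E
1 5 E
3 5 E
5 5 E
7 5 E
9 5 E
11 5 E
13 5 E
15 5 E
17 5 E
1 6 E
3 6 E
5 6 E
7 6 E
9 6 E
11 6 E
13 6 E
15 6 E
17 6 E
1 7 E
3 7 E
5 7 E
7 7 E
9 7 E
11 7 E
13 7 E
15 7 E
17 7 E
1 8 E
3 8 E
5 8 E
7 8 E
9 8 E
11 8 E
13 8 E
15 8 E
17 8 E
1 9 E
3 9 E
5 9 E
7 9 E
9 9 E
11 9 E
13 9 E
15 9 E
17 9 E
1 10 E
3 10 E
5 10 E
7 10 E
9 10 E
11 10 E
13 10 E
15 10 E
17 10 E
1 11 E
3 11 E
5 11 E
7 11 E
9 11 E
11 11 E
13 11 E
15 11 E
17 11 E
1 12 E
3 12 E
5 12 E
7 12 E
9 12 E
11 12 E
13 12 E
15 12 E
17 12 E
1 13 E
3 13 E
5 13 E
7 13 E
9 13 E
11 13 E
13 13 E
15 13 E
17 13 E
1 14 E
3 14 E
5 14 E
7 14 E
9 14 E
11 14 E
13 14 E
15 14 E
17 14 E
1 15 E
3 15 E
5 15 E
7 15 E
9 15 E
11 15 E
13 15 E
15 15 E
17 15 E
1 16 E
3 16 E
5 16 E
7 16 E
9 16 E
11 16 E
13 16 E
15 16 E
17 16 E
1 17 E
3 17 E
5 17 E
7 17 E
9 17 E
11 17 E
13 17 E
15 17 E
17 17 E
1 18 E
3 18 E
5 18 E
7 18 E
9 18 E
11 18 E
13 18 E
15 18 E
17 18 E
3 19 E
7 19 E
11 19 E
15 19 E
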