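navbasis-layout 1
width: 20
height: 20
goal: 10 12
reward: 1
walls:
5 9 N
6 9 N
7 9 N
8 9 N
9 9 N
10 9 N
11 9 N
12 9 N
13 9 N
14 9 N
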