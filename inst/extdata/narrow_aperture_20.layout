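navbasis-layout 1
width: 20
height: 20
goal: 10 2
reward: 1
walls:
9 0 E
9 1 E
9 2 E
9 3 E
9 4 E
9 5 E
9 6 E
9 7 E
9 8 E
9 9 E
9 10 E
9 11 E
9 12 E
9 13 E
9 14 E
9 15 E
9 16 E
9 17 E
9 18 E
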