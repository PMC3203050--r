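navbasis-layout 1
width: 20
height: 20
goal: 10 10
reward: 1
walls:
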