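alternative,C1,C2,C3,C4,C5,C6
A1,4,9,8,7,8,5
A2,8,7,7,8,6,8
A3,9,6,6,9,5,9
A4,7,8,7,8,7,7
A5,3,9,9,6,9,6
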