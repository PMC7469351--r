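r1 21
r2 18
r3 22
r4 19
r5 44
r6 39
r7 17
r8 23
r9 20
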