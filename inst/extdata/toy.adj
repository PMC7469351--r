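r1 r2
r2 r3
r1 r4
r2 r5
r3 r6
r4 r5
r5 r6
r4 r7
r5 r8
r6 r9
r7 r8
r8 r9
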