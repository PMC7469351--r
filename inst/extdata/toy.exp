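r1 20
r2 20
r3 20
r4 20
r5 20
r6 20
r7 20
r8 20
r9 20
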