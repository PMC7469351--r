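r1 0 0
r2 1 0
r3 2 0
r4 0 1
r5 1 1
r6 2 1
r7 0 2
r8 1 2
r9 2 2
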