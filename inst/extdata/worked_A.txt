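> A
5 -1 -2 6 -4 -8 $
-3 7 $
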