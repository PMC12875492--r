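# 6-node rewired star: spoke (0,2) rewired to (1,2)
0 1
0 3
0 4
0 5
1 2
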