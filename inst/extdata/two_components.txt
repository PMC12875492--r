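# a 4-node star plus a detached edge; exercises largest-component handling
a b
a c
a d
x y
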