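# node 1 excitatory
# node 2 inhibitory
# node 3 excitatory
# node 4 inhibitory
1 2 0.02
2 3 0.02
3 4 0.02
4 1 0.02
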