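"pre","post","postAll"
2,15,64
3,12,43
4,4,32
4,8,25
4,13,48
5,4,33
6,12,55
8,9,43
8,13,39
13,3,19
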