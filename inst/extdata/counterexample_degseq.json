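{"dA":[2,4,7],"dB":[2,4,7],"dC":[2,4,7]}
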