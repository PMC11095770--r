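{"classes":[[1,2,3],[4,5,6],[7,8,9]],"weights":[1,2,3,1,2,3,1,2,3],"b":6}
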