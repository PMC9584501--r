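name,row,col
E1,0,0
E2,0,1
E3,0,2
E4,1,0
E5,1,1
E6,1,2
E7,2,0
E8,2,1
E9,2,2
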