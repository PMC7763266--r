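series,x1,x2,x3,x4,x5
x1,0,0,0,0,0
x2,0,0,1,0,0
x3,1,1,0,1,1
x4,0,1,0,0,1
x5,0,1,0,0,0
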