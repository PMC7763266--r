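x1: gamma
x2: gamma
x3: gaussian
x4: gaussian
x5: poisson
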