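sex,band_lo,band_hi,weight
male,25,40,0.28
male,40,50,0.18
male,50,60,0.18
male,60,70,0.14
male,70,80,0.12
male,80,Inf,0.10
female,25,40,0.26
female,40,50,0.17
female,50,60,0.17
female,60,70,0.14
female,70,80,0.13
female,80,Inf,0.13
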