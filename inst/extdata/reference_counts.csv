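sex,category,n
female,poor,3407
female,intermediate,61966
female,healthy,108173
male,poor,3072
male,intermediate,55408
male,healthy,76657
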