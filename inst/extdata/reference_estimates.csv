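sex,exposure,label,reference,e_free
female,category,poor,healthy,31.46
female,category,intermediate,healthy,32.77
female,category,healthy,,33.26
male,category,poor,healthy,27.96
male,category,intermediate,healthy,29.72
male,category,healthy,,30.27
female,disorder,insomnia,without_insomnia,31.77
female,disorder,without_insomnia,,33.36
female,disorder,srbd,without_srbd,26.01
female,disorder,without_srbd,,33.34
female,disorder,other,without_other,31.91
female,disorder,without_other,,33.33
male,disorder,insomnia,without_insomnia,26.32
male,disorder,without_insomnia,,30.16
male,disorder,srbd,without_srbd,23.48
male,disorder,without_srbd,,30.21
male,disorder,other,without_other,29.19
male,disorder,without_other,,30.18
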