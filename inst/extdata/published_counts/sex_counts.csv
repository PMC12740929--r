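label,count
male,1442
female,1276
unknown,421
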