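term,n,ror,ror_low,ror_high,ebgm
Death,497,4.06,3.70,4.44,3.89
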