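label,count
other,816
hospitalization,741
life-threatening,93
disability,37
death,625
unknown,1119
congenital anomaly,1
required-intervention,207
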