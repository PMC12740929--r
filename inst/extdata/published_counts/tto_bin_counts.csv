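bin,count
<30,603
30-180,169
180-360,46
360-720,11
>720,8
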