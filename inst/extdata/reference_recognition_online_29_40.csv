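subject,forward,right,left,stop
S11,10,9,10,9
S12,9,10,9,9
S13,8,9,9,10
S14,10,10,9,9
S15,9,9,9,8
S16,9,9,9,9
S17,9,8,9,9
S18,9,9,9,9
S19,10,9,9,9
S20,10,10,9,9
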