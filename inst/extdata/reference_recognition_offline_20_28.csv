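subject,forward,right,left,stop
S1,9,9,10,9
S2,10,10,10,9
S3,10,10,10,10
S4,10,9,10,9
S5,10,9,9,9
S6,9,10,10,10
S7,10,10,9,9
S8,10,9,9,10
S9,10,10,9,9
S10,10,10,10,10
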