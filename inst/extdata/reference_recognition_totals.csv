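table,FORWARD,RIGHT,LEFT,STOP,wrong
offline_20_28,98,96,96,94,16
offline_29_40,95,94,93,92,25
online_20_28,95,94,94,93,24
online_29_40,93,92,91,90,34
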