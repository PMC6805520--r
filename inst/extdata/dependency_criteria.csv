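,ES,IS,TS
ES,0.00,0.25,0.25
IS,0.50,0.00,0.75
TS,0.50,0.75,0.00
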