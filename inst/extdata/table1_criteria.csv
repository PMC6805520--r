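,ES,IS,TS
ES,1,3,2
IS,1/3,1,1/2
TS,1/2,2,1
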