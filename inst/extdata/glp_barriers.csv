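enzyme,step,barrier
WT,1,13.4
WT,2,15.8
WT,3,22.1
F1209Y,1,13.8
F1209Y,2,17.4
Y1124F,1,13.9
Y1124F,2,15.9
Y1124F,3,13.3
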