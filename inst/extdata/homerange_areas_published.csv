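radio,sex,n_locations,area_ha
R1,M,12,0.441
R3,M,10,0.328
R6,U,10,0.270
R7,M,10,0.277
R8,M,10,2.652
R10,M,10,0.271
R11,M,10,0.204
R13,F,10,0.150
R15,F,10,0.341
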