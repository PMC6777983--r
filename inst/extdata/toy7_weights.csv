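region,R1,R2,R3,R4,R5,R6,R7
R1,0,5,2,0,3.5,0,0
R2,4,0,3,0.5,0,0,1.1
R3,1.5,0,0,1,0,0,0
R4,2.5,0,0,0,0,0.6,0
R5,0,1.8,0,0,0,2,0
R6,0,0,0,0,2.2,0,1.2
R7,0,0.9,0,0,0.8,0,0
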