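,asm,contrast,correlation,idm,entropy
asm,1,-0.504,0.084,0.954,-0.907
contrast,-0.504,1,-0.604,-0.350,0.772
correlation,0.084,-0.604,1,-0.041,-0.361
idm,0.954,-0.350,-0.041,1,-0.786
entropy,-0.907,0.772,-0.361,-0.786,1
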