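,asm,contrast,correlation,idm,entropy
asm,1,-0.851,0.779,0.900,-0.935
contrast,-0.851,1,-0.830,-0.780,0.925
correlation,0.779,-0.830,1,0.788,-0.859
idm,0.900,-0.780,0.788,1,-0.927
entropy,-0.935,0.925,-0.859,-0.927,1
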