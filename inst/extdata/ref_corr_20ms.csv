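,asm,contrast,correlation,idm,entropy
asm,1,-0.526,0.046,0.989,-0.967
contrast,-0.526,1,-0.778,-0.438,0.696
correlation,0.046,-0.778,1,-0.061,-0.275
idm,0.989,-0.438,-0.061,1,-0.932
entropy,-0.967,0.696,-0.275,-0.932,1
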