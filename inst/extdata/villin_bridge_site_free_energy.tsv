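label	state	delta_G
GLU45 sites	extended	-4.24
LYS48 sites	extended	-7.64
GLU45-LYS48 bridge	native	-13.69
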