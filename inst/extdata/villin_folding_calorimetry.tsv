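quantity	value	unit
dH_at_Tm	-31	kcal/mol
Tm	74.4	degC
Cp	0.374	kcal/mol/K
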