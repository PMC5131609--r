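treatment	state	n_sites	delta_G_mean	delta_G_std
CHARMM22/TIP3P	native	442	-1.25	1.21
CHARMM22/TIP3P	extended	875	-1.04	0.91
CHARMM36/TIP3P	native	440	-1.84	1.62
CHARMM36/TIP3P	extended	886	-1.42	1.25
CHARMM36/TIP4P-2005	native	437	-2.21	1.66
CHARMM36/TIP4P-2005	extended	871	-1.78	1.32
CHARMM22/TIP3P/NaCl	native	360	-1.85	1.69
CHARMM22/TIP3P/NaCl	intermediate1	378	-1.79	1.56
CHARMM22/TIP3P/NaCl	intermediate2	433	-1.63	1.45
CHARMM22/TIP3P/NaCl	intermediate3	468	-1.58	1.48
CHARMM22/TIP3P/NaCl	extended	708	-1.41	1.32
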