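treatment	hbond_total	hbond_persistent	nonpolar_total	nonpolar_persistent	coophyd_total	coophyd_persistent
CHARMM22/TIP3P	142	27	607	72	474	17
CHARMM36/TIP3P	130	30	526	71	470	16
CHARMM36/TIP4P-2005	146	24	532	84	531	59
CHARMM22/TIP3P/NaCl	127	24	533	73	438	15
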