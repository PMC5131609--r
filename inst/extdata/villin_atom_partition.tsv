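treatment	delta_E_total	delta_E_polar	delta_E_nonpolar
CHARMM22/TIP3P	-63.8	-34.3	-29.5
CHARMM36/TIP3P	-62.9	-31.3	-31.6
CHARMM36/TIP4P-2005	-49.7	-21.0	-28.7
CHARMM22/TIP3P/NaCl	-62.0	-31.5	-30.5
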