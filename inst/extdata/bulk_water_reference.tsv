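water_model	nacl_mM	E_bulk	G_bulk	minus_T_S_bulk
TIP3P	0	-9.8	-6.3	3.5
TIP3P	50	-10.2	-6.5	3.8
TIP3P	100	-10.6	-6.5	4.1
TIP3P	150	-11.1	-6.3	4.7
TIP3P	200	-11.4	-6.5	5.0
TIP4P-2005	0	-11.6	-7.0	4.6
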