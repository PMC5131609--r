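interaction	term	E_native	E_native_std	E_extended	E_extended_std
protein-protein	bonded	573.8	1.0	578.0	1.2
protein-protein	non-bonded	-642.6	29.6	-165.5	24.5
protein-water	non-bonded	-1465.2	46.6	-2106.7	57.6
water-water	non-bonded	-77156.9	33.5	-76920.8	52.5
protein-salt	non-bonded	-179.1	28.3	-367.2	77.8
water-salt	non-bonded	-9085.3	46.5	-8974.0	61.2
salt-salt	non-bonded	-1030.3	20.8	-993.4	28.8
total	all	-88985.7	16.0	-88949.6	16.5
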