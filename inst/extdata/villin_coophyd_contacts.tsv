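atom1	atom2	persistence	persistence_std	E_native	E_native_std	E_extended	E_extended_std	delta_E
LEU42 O	ARG55 HH11/HH21	0.63	0.25	-67.22	0.38	-68.4	0.4	1.2
ASP44 HN	ASP44 OD1/OD2	0.58	0.14	-34.01	0.31	-31.3	0.3	-2.7
LYS48 O	ALA49 O	0.64	0.08	3.88	0.30	3.9	0.2	-0.1
ALA49 O	VAL50 O	0.92	0.08	0.95	0.22	0.8	0.2	0.1
VAL50 O	LYS73 HZ1/HZ2/HZ3	0.85	0.11	-5.18	0.24	-5.3	0.2	0.1
ALA59 O	LEU61 O	0.89	0.05	17.08	0.25	16.4	0.2	0.7
ALA59 O	GLN66 HE21	0.87	0.08	-16.43	0.30	-16.9	0.2	0.5
GLN66 OE1	LYS70 HZ1/HZ2/HZ3	0.68	0.13	-31.91	0.20	-31.2	0.2	-0.7
LYS71 O	GLU72 O	0.62	0.06	1.68	0.20	0.9	0.2	0.7
GLY74 O	PHE76 OT1/OT2	0.69	0.14	-28.51	0.38	-27.8	0.3	-0.7
LEU75 O	PHE76 OT1/OT2	0.85	0.10	-20.31	0.33	-20.5	0.3	0.2
ASP44 OD1/OD2	ARG55 HN	0.51	0.20	-29.87	0.26	-29.0	0.4	-0.9
ASP44 OD1/OD2	SER56 HN	0.86	0.16	-22.47	0.23	-22.2	0.4	-0.3
GLU72 OE1/OE2	LYS73 HZ1/HZ2/HZ3	0.61	0.20	-23.59	0.30	-23.2	0.3	-0.4
GLU45 OE1/OE2	LYS48 HZ1/HZ2/HZ3	0.69	0.31	-23.93	0.72	-23.2	0.3	-0.7
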