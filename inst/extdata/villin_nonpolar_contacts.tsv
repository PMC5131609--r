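atom1	atom2	persistence	persistence_std	E_native	E_native_std	E_extended	E_extended_std	delta_E
MET53 CE	LEU61 CD1/LEU61 CD2	1.10	0.14	-11.4	0.1	-10.7	0.1	-0.7
LEU61 CD1/LEU61 CD2	LYS65 CB	1.11	0.49	-8.4	0.1	-7.5	0.1	-0.9
PHE51 CE1/PHE51 CE2	LEU75 CD1/LEU75 CD2	1.13	0.10	-6.1	0.1	-5.9	0.1	-0.3
MET53 SD	LEU61 CD1/LEU61 CD2	1.14	0.12	-12.6	0.1	-11.2	0.1	-1.4
PHE47 CE1/PHE47 CE2	PHE58 CD1/PHE58 CD2	1.22	0.12	0.0	0.1	0.4	0.1	-0.4
PHE51 CE1/PHE51 CE2	PHE58 CE1/PHE58 CE2	1.25	0.22	3.1	0.1	3.1	0.1	0.0
VAL50 CG1/VAL50 CG2	PHE51 CE1/PHE51 CE2	1.28	0.18	-2.0	0.1	-1.7	0.1	-0.3
VAL50 CG1/VAL50 CG2	PHE51 CD1/PHE51 CD2	1.31	0.16	-4.7	0.1	-4.4	0.1	-0.4
PHE51 CD1/PHE51 CD2	PHE58 CE1/PHE58 CE2	1.34	0.20	0.4	0.1	0.4	0.1	0.0
PHE58 CE1/PHE58 CE2	GLN66 CG	1.48	0.12	-10.5	0.1	-9.9	0.1	-0.6
PHE47 CE1/PHE47 CE2	PHE51 CE1/PHE51 CE2	1.51	0.08	2.9	0.1	3.1	0.1	-0.2
PHE47 CE1/PHE47 CE2	ARG55 CG	1.57	0.12	-3.4	0.1	-2.9	0.1	-0.5
PHE47 CD1/PHE47 CD2	PHE51 CD1/PHE51 CD2	1.60	0.13	-2.8	0.1	-2.3	0.1	-0.5
PHE47 CE1/PHE47 CE2	PHE51 CD1/PHE51 CD2	1.76	0.22	0.1	0.1	0.4	0.1	-0.3
PHE47 CD1/PHE47 CD2	ARG55 CG	1.86	0.15	-6.1	0.1	-5.6	0.1	-0.5
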