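donor	acceptor	persistence	persistence_std	E_native	E_native_std	E_extended	E_extended_std	delta_E
PHE47 N	SER43 O	0.96	0.06	-6.1	0.3	-5.4	0.2	-0.7
LYS48 N	ASP44 O	0.99	0.01	3.9	0.2	4.5	0.3	-0.6
PHE51 N	PHE47 O	0.99	0.01	0.3	0.3	2.1	0.2	-1.7
ARG55 NE	ASP44 OD1/ASP44 OD2	1.00	0.00	-100.1	0.2	-99.2	0.4	-1.0
ARG55 NH1/ARG55 NH2	ASP44 OD1/ASP44 OD2	1.00	0.00	-97.1	0.0	-94.1	0.4	-3.0
PHE58 N	THR54 O	1.00	0.01	-8.7	0.2	-7.8	0.2	-1.0
ALA59 N	ARG55 O	0.96	0.02	-2.2	0.2	-0.8	0.2	-1.4
GLN66 N	PRO62 O	0.99	0.01	-4.9	0.2	-3.9	0.2	-0.9
GLN67 N	LEU63 O	1.00	0.00	0.6	0.2	1.1	0.3	-0.5
HIS68 N	TRP64 O	0.99	0.01	2.6	0.2	3.8	0.2	-1.2
LEU69 N	LYS65 O	0.99	0.01	0.4	0.2	1.5	0.2	-1.1
LYS70 N	GLN66 O	0.99	0.01	0.7	0.2	1.7	0.2	-1.0
LYS71 N	GLN67 O	0.99	0.01	0.4	0.3	1.8	0.2	-1.4
GLU72 N	HIS68 O	0.99	0.01	-2.0	0.3	-0.9	0.2	-1.1
LYS73 N	LEU69 O	0.95	0.03	1.6	0.2	1.3	0.4	0.3
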