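residue_name	atom_name	radius_A	charge_e	lj_epsilon	lj_rmin_half
*	N	1.55	-0.16	0.20	1.85
*	CA	1.70	0.16	0.07	2.00
*	C	1.70	0.51	0.07	2.00
*	O	1.52	-0.51	0.12	1.70
*	OXT	1.52	-0.51	0.12	1.70
*	CB	1.70	0.00	0.07	2.00
MET	CG	1.70	0.06	0.07	2.00
MET	SD	1.80	-0.12	0.45	2.00
MET	CE	1.70	0.06	0.07	2.00
MSX	CG	1.70	0.14	0.07	2.00
MSX	SD	1.80	0.30	0.45	2.00
MSX	OD	1.52	-0.58	0.12	1.70
MSX	CE	1.70	0.14	0.07	2.00
HOH	O	1.52	-0.834	0.152	1.77
HOH	H1	1.20	0.417	0.046	0.22
HOH	H2	1.20	0.417	0.046	0.22
*	@C	1.70	0.00	0.07	2.00
*	@N	1.55	0.00	0.20	1.85
*	@O	1.52	0.00	0.12	1.70
*	@S	1.80	0.00	0.45	2.00
*	@H	1.20	0.00	0.03	1.20
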