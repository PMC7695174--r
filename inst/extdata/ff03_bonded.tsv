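# Equilibrium bonded parameters transcribed from the Amber ff03 set
# (heavy atoms only).  kind: bond (value in nm) or angle (value in degrees).
# residue "*" = any residue; a residue-specific row takes precedence.
# Generic side-chain rows use the dominant atom-type class (CT-CT etc.);
# aromatic / carboxylate / amide groups get residue-specific rows.
kind	residue	atoms	value
bond	*	N-CA	0.1449
bond	*	CA-C	0.1522
bond	*	C-O	0.1229
bond	*	C-N	0.1335
bond	*	C-OXT	0.1250
bond	*	CA-CB	0.1526
bond	*	CB-CG	0.1526
bond	*	CB-CG1	0.1526
bond	*	CB-CG2	0.1526
bond	*	CG-CD	0.1526
bond	*	CG-CD1	0.1526
bond	*	CG-CD2	0.1526
bond	*	CG1-CD1	0.1526
bond	*	CD-CE	0.1526
bond	*	CE-NZ	0.1471
bond	*	CB-OG	0.1410
bond	*	CB-OG1	0.1410
bond	*	CB-SG	0.1810
bond	*	CG-SD	0.1810
bond	*	SD-CE	0.1810
bond	*	CD-NE	0.1463
bond	ARG	NE-CZ	0.1340
bond	ARG	CZ-NH1	0.1340
bond	ARG	CZ-NH2	0.1340
bond	ASP	CG-OD1	0.1250
bond	ASP	CG-OD2	0.1250
bond	ASN	CG-OD1	0.1229
bond	ASN	CG-ND2	0.1335
bond	GLU	CD-OE1	0.1250
bond	GLU	CD-OE2	0.1250
bond	GLN	CD-OE1	0.1229
bond	GLN	CD-NE2	0.1335
bond	PHE	CB-CG	0.1510
bond	PHE	CG-CD1	0.1400
bond	PHE	CG-CD2	0.1400
bond	PHE	CD1-CE1	0.1400
bond	PHE	CD2-CE2	0.1400
bond	PHE	CE1-CZ	0.1400
bond	PHE	CE2-CZ	0.1400
bond	TYR	CB-CG	0.1510
bond	TYR	CG-CD1	0.1400
bond	TYR	CG-CD2	0.1400
bond	TYR	CD1-CE1	0.1400
bond	TYR	CD2-CE2	0.1400
bond	TYR	CE1-CZ	0.1400
bond	TYR	CE2-CZ	0.1400
bond	TYR	CZ-OH	0.1364
bond	HIS	CB-CG	0.1504
bond	HIS	CG-ND1	0.1385
bond	HIS	CG-CD2	0.1400
bond	HIS	ND1-CE1	0.1343
bond	HIS	CD2-NE2	0.1394
bond	HIS	CE1-NE2	0.1335
bond	TRP	CB-CG	0.1495
bond	TRP	CG-CD1	0.1352
bond	TRP	CG-CD2	0.1459
bond	TRP	CD1-NE1	0.1381
bond	TRP	NE1-CE2	0.1380
bond	TRP	CD2-CE2	0.1419
bond	TRP	CD2-CE3	0.1398
bond	TRP	CE3-CZ3	0.1400
bond	TRP	CE2-CZ2	0.1400
bond	TRP	CZ2-CH2	0.1400
bond	TRP	CZ3-CH2	0.1400
bond	PRO	CD-N	0.1463
angle	*	N-CA-C	110.1
angle	*	CA-C-N	116.6
angle	*	CA-C-O	120.4
angle	*	O-C-N	122.9
angle	*	C-N-CA	121.9
angle	*	N-CA-CB	109.7
angle	*	CB-CA-C	111.1
angle	*	CA-C-OXT	117.0
angle	*	O-C-OXT	126.0
angle	*	CA-CB-CG	109.5
angle	*	CA-CB-CG1	109.5
angle	*	CA-CB-CG2	109.5
angle	*	CG1-CB-CG2	109.5
angle	*	CB-CG-CD	109.5
angle	*	CB-CG-CD1	109.5
angle	*	CB-CG-CD2	109.5
angle	*	CG-CD-CE	109.5
angle	*	CD-CE-NZ	111.2
angle	*	CA-CB-OG	109.5
angle	*	CA-CB-OG1	109.5
angle	*	CA-CB-SG	108.6
angle	*	CB-CG-SD	114.7
angle	*	CG-SD-CE	98.9
angle	ASP	CB-CG-OD1	117.0
angle	ASP	CB-CG-OD2	117.0
angle	ASP	OD1-CG-OD2	126.0
angle	ASN	CB-CG-OD1	120.4
angle	ASN	CB-CG-ND2	116.6
angle	ASN	OD1-CG-ND2	122.9
angle	GLU	CG-CD-OE1	117.0
angle	GLU	CG-CD-OE2	117.0
angle	GLU	OE1-CD-OE2	126.0
angle	GLN	CG-CD-OE1	120.4
angle	GLN	CG-CD-NE2	116.6
angle	GLN	OE1-CD-NE2	122.9
angle	ARG	CG-CD-NE	111.2
angle	ARG	CD-NE-CZ	123.2
angle	ARG	NE-CZ-NH1	120.0
angle	ARG	NE-CZ-NH2	120.0
angle	ARG	NH1-CZ-NH2	120.0
angle	PHE	CB-CG-CD1	120.0
angle	PHE	CB-CG-CD2	120.0
angle	PHE	CD1-CG-CD2	120.0
angle	PHE	CG-CD1-CE1	120.0
angle	PHE	CG-CD2-CE2	120.0
angle	PHE	CD1-CE1-CZ	120.0
angle	PHE	CD2-CE2-CZ	120.0
angle	PHE	CE1-CZ-CE2	120.0
angle	TYR	CB-CG-CD1	120.0
angle	TYR	CB-CG-CD2	120.0
angle	TYR	CD1-CG-CD2	120.0
angle	TYR	CG-CD1-CE1	120.0
angle	TYR	CG-CD2-CE2	120.0
angle	TYR	CD1-CE1-CZ	120.0
angle	TYR	CD2-CE2-CZ	120.0
angle	TYR	CE1-CZ-CE2	120.0
angle	TYR	CE1-CZ-OH	120.0
angle	TYR	CE2-CZ-OH	120.0
angle	HIS	CB-CG-ND1	122.2
angle	HIS	CB-CG-CD2	131.0
angle	HIS	ND1-CG-CD2	106.8
angle	HIS	CG-ND1-CE1	109.0
angle	HIS	CG-CD2-NE2	107.0
angle	HIS	ND1-CE1-NE2	108.0
angle	HIS	CD2-NE2-CE1	109.2
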