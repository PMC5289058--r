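# tcrdom nonbonded/torsion parameter table, version 1
# OPLS-style all-atom functional form:
#   E = sum_pairs 4*eps*((s/r)^12 - (s/r)^6) + k_C*qi*qj/r  (geometric-mean
#   combination for sigma and epsilon, 0.5/0.5 scaling of 1-4 pairs)
# Records (tab separated):
#   ATOM    res name type charge sigma epsilon
#   BOND    res name1 name2
#   FORMAL  res charge
#   TORSION t1 t2 t3 t4 K n phase_deg       (E = K*(1 + cos(n*phi - phase)))
# charge in e, sigma in Angstrom, epsilon in kcal/mol.
VERSION	1
# ---- torsion terms for the carboxamide chi rotation axis ----
TORSION	CT	CT	C	O	0.25	2	180
TORSION	CT	CT	C	N	0.25	2	180
# ---- glycine ----
ATOM	GLY	N	N	-0.500	3.25	0.170
ATOM	GLY	H	H	0.300	1.00	0.000
ATOM	GLY	CA	CT	0.080	3.50	0.066
ATOM	GLY	HA2	HC	0.060	2.50	0.030
ATOM	GLY	HA3	HC	0.060	2.50	0.030
ATOM	GLY	C	C	0.500	3.75	0.105
ATOM	GLY	O	O	-0.500	2.96	0.210
BOND	GLY	N	H
BOND	GLY	N	CA
BOND	GLY	CA	HA2
BOND	GLY	CA	HA3
BOND	GLY	CA	C
BOND	GLY	C	O
FORMAL	GLY	0
# ---- alanine ----
ATOM	ALA	N	N	-0.500	3.25	0.170
ATOM	ALA	H	H	0.300	1.00	0.000
ATOM	ALA	CA	CT	0.140	3.50	0.066
ATOM	ALA	HA	HC	0.060	2.50	0.030
ATOM	ALA	CB	CT	-0.180	3.50	0.066
ATOM	ALA	HB1	HC	0.060	2.50	0.030
ATOM	ALA	HB2	HC	0.060	2.50	0.030
ATOM	ALA	HB3	HC	0.060	2.50	0.030
ATOM	ALA	C	C	0.500	3.75	0.105
ATOM	ALA	O	O	-0.500	2.96	0.210
BOND	ALA	N	H
BOND	ALA	N	CA
BOND	ALA	CA	HA
BOND	ALA	CA	CB
BOND	ALA	CB	HB1
BOND	ALA	CB	HB2
BOND	ALA	CB	HB3
BOND	ALA	CA	C
BOND	ALA	C	O
FORMAL	ALA	0
# ---- serine ----
ATOM	SER	N	N	-0.500	3.25	0.170
ATOM	SER	H	H	0.300	1.00	0.000
ATOM	SER	CA	CT	0.140	3.50	0.066
ATOM	SER	HA	HC	0.060	2.50	0.030
ATOM	SER	CB	CT	0.145	3.50	0.066
ATOM	SER	HB2	HC	0.060	2.50	0.030
ATOM	SER	HB3	HC	0.060	2.50	0.030
ATOM	SER	OG	OH	-0.683	3.12	0.170
ATOM	SER	HG	HO	0.418	1.00	0.000
ATOM	SER	C	C	0.500	3.75	0.105
ATOM	SER	O	O	-0.500	2.96	0.210
BOND	SER	N	H
BOND	SER	N	CA
BOND	SER	CA	HA
BOND	SER	CA	CB
BOND	SER	CB	HB2
BOND	SER	CB	HB3
BOND	SER	CB	OG
BOND	SER	OG	HG
BOND	SER	CA	C
BOND	SER	C	O
FORMAL	SER	0
# ---- threonine ----
ATOM	THR	N	N	-0.500	3.25	0.170
ATOM	THR	H	H	0.300	1.00	0.000
ATOM	THR	CA	CT	0.140	3.50	0.066
ATOM	THR	HA	HC	0.060	2.50	0.030
ATOM	THR	CB	CT	0.205	3.50	0.066
ATOM	THR	HB	HC	0.060	2.50	0.030
ATOM	THR	OG1	OH	-0.683	3.12	0.170
ATOM	THR	HG1	HO	0.418	1.00	0.000
ATOM	THR	CG2	CT	-0.180	3.50	0.066
ATOM	THR	HG21	HC	0.060	2.50	0.030
ATOM	THR	HG22	HC	0.060	2.50	0.030
ATOM	THR	HG23	HC	0.060	2.50	0.030
ATOM	THR	C	C	0.500	3.75	0.105
ATOM	THR	O	O	-0.500	2.96	0.210
BOND	THR	N	H
BOND	THR	N	CA
BOND	THR	CA	HA
BOND	THR	CA	CB
BOND	THR	CB	HB
BOND	THR	CB	OG1
BOND	THR	OG1	HG1
BOND	THR	CB	CG2
BOND	THR	CG2	HG21
BOND	THR	CG2	HG22
BOND	THR	CG2	HG23
BOND	THR	CA	C
BOND	THR	C	O
FORMAL	THR	0
# ---- valine ----
ATOM	VAL	N	N	-0.500	3.25	0.170
ATOM	VAL	H	H	0.300	1.00	0.000
ATOM	VAL	CA	CT	0.140	3.50	0.066
ATOM	VAL	HA	HC	0.060	2.50	0.030
ATOM	VAL	CB	CT	-0.060	3.50	0.066
ATOM	VAL	HB	HC	0.060	2.50	0.030
ATOM	VAL	CG1	CT	-0.180	3.50	0.066
ATOM	VAL	HG11	HC	0.060	2.50	0.030
ATOM	VAL	HG12	HC	0.060	2.50	0.030
ATOM	VAL	HG13	HC	0.060	2.50	0.030
ATOM	VAL	CG2	CT	-0.180	3.50	0.066
ATOM	VAL	HG21	HC	0.060	2.50	0.030
ATOM	VAL	HG22	HC	0.060	2.50	0.030
ATOM	VAL	HG23	HC	0.060	2.50	0.030
ATOM	VAL	C	C	0.500	3.75	0.105
ATOM	VAL	O	O	-0.500	2.96	0.210
BOND	VAL	N	H
BOND	VAL	N	CA
BOND	VAL	CA	HA
BOND	VAL	CA	CB
BOND	VAL	CB	HB
BOND	VAL	CB	CG1
BOND	VAL	CG1	HG11
BOND	VAL	CG1	HG12
BOND	VAL	CG1	HG13
BOND	VAL	CB	CG2
BOND	VAL	CG2	HG21
BOND	VAL	CG2	HG22
BOND	VAL	CG2	HG23
BOND	VAL	CA	C
BOND	VAL	C	O
FORMAL	VAL	0
# ---- leucine ----
ATOM	LEU	N	N	-0.500	3.25	0.170
ATOM	LEU	H	H	0.300	1.00	0.000
ATOM	LEU	CA	CT	0.140	3.50	0.066
ATOM	LEU	HA	HC	0.060	2.50	0.030
ATOM	LEU	CB	CT	-0.120	3.50	0.066
ATOM	LEU	HB2	HC	0.060	2.50	0.030
ATOM	LEU	HB3	HC	0.060	2.50	0.030
ATOM	LEU	CG	CT	-0.060	3.50	0.066
ATOM	LEU	HG	HC	0.060	2.50	0.030
ATOM	LEU	CD1	CT	-0.180	3.50	0.066
ATOM	LEU	HD11	HC	0.060	2.50	0.030
ATOM	LEU	HD12	HC	0.060	2.50	0.030
ATOM	LEU	HD13	HC	0.060	2.50	0.030
ATOM	LEU	CD2	CT	-0.180	3.50	0.066
ATOM	LEU	HD21	HC	0.060	2.50	0.030
ATOM	LEU	HD22	HC	0.060	2.50	0.030
ATOM	LEU	HD23	HC	0.060	2.50	0.030
ATOM	LEU	C	C	0.500	3.75	0.105
ATOM	LEU	O	O	-0.500	2.96	0.210
BOND	LEU	N	H
BOND	LEU	N	CA
BOND	LEU	CA	HA
BOND	LEU	CA	CB
BOND	LEU	CB	HB2
BOND	LEU	CB	HB3
BOND	LEU	CB	CG
BOND	LEU	CG	HG
BOND	LEU	CG	CD1
BOND	LEU	CD1	HD11
BOND	LEU	CD1	HD12
BOND	LEU	CD1	HD13
BOND	LEU	CG	CD2
BOND	LEU	CD2	HD21
BOND	LEU	CD2	HD22
BOND	LEU	CD2	HD23
BOND	LEU	CA	C
BOND	LEU	C	O
FORMAL	LEU	0
# ---- isoleucine ----
ATOM	ILE	N	N	-0.500	3.25	0.170
ATOM	ILE	H	H	0.300	1.00	0.000
ATOM	ILE	CA	CT	0.140	3.50	0.066
ATOM	ILE	HA	HC	0.060	2.50	0.030
ATOM	ILE	CB	CT	-0.060	3.50	0.066
ATOM	ILE	HB	HC	0.060	2.50	0.030
ATOM	ILE	CG1	CT	-0.120	3.50	0.066
ATOM	ILE	HG12	HC	0.060	2.50	0.030
ATOM	ILE	HG13	HC	0.060	2.50	0.030
ATOM	ILE	CG2	CT	-0.180	3.50	0.066
ATOM	ILE	HG21	HC	0.060	2.50	0.030
ATOM	ILE	HG22	HC	0.060	2.50	0.030
ATOM	ILE	HG23	HC	0.060	2.50	0.030
ATOM	ILE	CD1	CT	-0.180	3.50	0.066
ATOM	ILE	HD11	HC	0.060	2.50	0.030
ATOM	ILE	HD12	HC	0.060	2.50	0.030
ATOM	ILE	HD13	HC	0.060	2.50	0.030
ATOM	ILE	C	C	0.500	3.75	0.105
ATOM	ILE	O	O	-0.500	2.96	0.210
BOND	ILE	N	H
BOND	ILE	N	CA
BOND	ILE	CA	HA
BOND	ILE	CA	CB
BOND	ILE	CB	HB
BOND	ILE	CB	CG1
BOND	ILE	CG1	HG12
BOND	ILE	CG1	HG13
BOND	ILE	CG1	CD1
BOND	ILE	CD1	HD11
BOND	ILE	CD1	HD12
BOND	ILE	CD1	HD13
BOND	ILE	CB	CG2
BOND	ILE	CG2	HG21
BOND	ILE	CG2	HG22
BOND	ILE	CG2	HG23
BOND	ILE	CA	C
BOND	ILE	C	O
FORMAL	ILE	0
# ---- asparagine ----
ATOM	ASN	N	N	-0.500	3.25	0.170
ATOM	ASN	H	H	0.300	1.00	0.000
ATOM	ASN	CA	CT	0.140	3.50	0.066
ATOM	ASN	HA	HC	0.060	2.50	0.030
ATOM	ASN	CB	CT	-0.120	3.50	0.066
ATOM	ASN	HB2	HC	0.060	2.50	0.030
ATOM	ASN	HB3	HC	0.060	2.50	0.030
ATOM	ASN	CG	C	0.500	3.75	0.105
ATOM	ASN	OD1	O	-0.500	2.96	0.210
ATOM	ASN	ND2	N	-0.760	3.25	0.170
ATOM	ASN	HD21	H	0.380	1.00	0.000
ATOM	ASN	HD22	H	0.380	1.00	0.000
ATOM	ASN	C	C	0.500	3.75	0.105
ATOM	ASN	O	O	-0.500	2.96	0.210
BOND	ASN	N	H
BOND	ASN	N	CA
BOND	ASN	CA	HA
BOND	ASN	CA	CB
BOND	ASN	CB	HB2
BOND	ASN	CB	HB3
BOND	ASN	CB	CG
BOND	ASN	CG	OD1
BOND	ASN	CG	ND2
BOND	ASN	ND2	HD21
BOND	ASN	ND2	HD22
BOND	ASN	CA	C
BOND	ASN	C	O
FORMAL	ASN	0
# ---- glutamine ----
ATOM	GLN	N	N	-0.500	3.25	0.170
ATOM	GLN	H	H	0.300	1.00	0.000
ATOM	GLN	CA	CT	0.140	3.50	0.066
ATOM	GLN	HA	HC	0.060	2.50	0.030
ATOM	GLN	CB	CT	-0.120	3.50	0.066
ATOM	GLN	HB2	HC	0.060	2.50	0.030
ATOM	GLN	HB3	HC	0.060	2.50	0.030
ATOM	GLN	CG	CT	-0.120	3.50	0.066
ATOM	GLN	HG2	HC	0.060	2.50	0.030
ATOM	GLN	HG3	HC	0.060	2.50	0.030
ATOM	GLN	CD	C	0.500	3.75	0.105
ATOM	GLN	OE1	O	-0.500	2.96	0.210
ATOM	GLN	NE2	N	-0.760	3.25	0.170
ATOM	GLN	HE21	H	0.380	1.00	0.000
ATOM	GLN	HE22	H	0.380	1.00	0.000
ATOM	GLN	C	C	0.500	3.75	0.105
ATOM	GLN	O	O	-0.500	2.96	0.210
BOND	GLN	N	H
BOND	GLN	N	CA
BOND	GLN	CA	HA
BOND	GLN	CA	CB
BOND	GLN	CB	HB2
BOND	GLN	CB	HB3
BOND	GLN	CB	CG
BOND	GLN	CG	HG2
BOND	GLN	CG	HG3
BOND	GLN	CG	CD
BOND	GLN	CD	OE1
BOND	GLN	CD	NE2
BOND	GLN	NE2	HE21
BOND	GLN	NE2	HE22
BOND	GLN	CA	C
BOND	GLN	C	O
FORMAL	GLN	0
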