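residue	atom	element	charge	donor	acceptor
ALA	N	N	0	1	0
ALA	CA	C	0	0	0
ALA	C	C	0	0	0
ALA	O	O	0	0	1
ALA	OXT	O	0	0	1
ALA	CB	C	0	0	0
ALA	H	H	0	0	0
ALA	HA	H	0	0	0
ARG	N	N	0	1	0
ARG	CA	C	0	0	0
ARG	C	C	0	0	0
ARG	O	O	0	0	1
ARG	OXT	O	0	0	1
ARG	CB	C	0	0	0
ARG	CG	C	0	0	0
ARG	CD	C	0	0	0
ARG	NE	N	0	1	0
ARG	CZ	C	0	0	0
ARG	NH1	N	0.5	1	0
ARG	NH2	N	0.5	1	0
ARG	H	H	0	0	0
ARG	HA	H	0	0	0
ARG	HE	H	0	0	0
ARG	HH11	H	0	0	0
ARG	HH12	H	0	0	0
ARG	HH21	H	0	0	0
ARG	HH22	H	0	0	0
ASN	N	N	0	1	0
ASN	CA	C	0	0	0
ASN	C	C	0	0	0
ASN	O	O	0	0	1
ASN	OXT	O	0	0	1
ASN	CB	C	0	0	0
ASN	CG	C	0	0	0
ASN	OD1	O	0	0	1
ASN	ND2	N	0	1	0
ASN	H	H	0	0	0
ASN	HA	H	0	0	0
ASN	HD21	H	0	0	0
ASN	HD22	H	0	0	0
ASP	N	N	0	1	0
ASP	CA	C	0	0	0
ASP	C	C	0	0	0
ASP	O	O	0	0	1
ASP	OXT	O	0	0	1
ASP	CB	C	0	0	0
ASP	CG	C	0	0	0
ASP	OD1	O	-0.5	0	1
ASP	OD2	O	-0.5	0	1
ASP	H	H	0	0	0
ASP	HA	H	0	0	0
CYS	N	N	0	1	0
CYS	CA	C	0	0	0
CYS	C	C	0	0	0
CYS	O	O	0	0	1
CYS	OXT	O	0	0	1
CYS	CB	C	0	0	0
CYS	SG	S	0	1	0
CYS	H	H	0	0	0
CYS	HA	H	0	0	0
CYS	HG	H	0	0	0
GLN	N	N	0	1	0
GLN	CA	C	0	0	0
GLN	C	C	0	0	0
GLN	O	O	0	0	1
GLN	OXT	O	0	0	1
GLN	CB	C	0	0	0
GLN	CG	C	0	0	0
GLN	CD	C	0	0	0
GLN	OE1	O	0	0	1
GLN	NE2	N	0	1	0
GLN	H	H	0	0	0
GLN	HA	H	0	0	0
GLN	HE21	H	0	0	0
GLN	HE22	H	0	0	0
GLU	N	N	0	1	0
GLU	CA	C	0	0	0
GLU	C	C	0	0	0
GLU	O	O	0	0	1
GLU	OXT	O	0	0	1
GLU	CB	C	0	0	0
GLU	CG	C	0	0	0
GLU	CD	C	0	0	0
GLU	OE1	O	-0.5	0	1
GLU	OE2	O	-0.5	0	1
GLU	H	H	0	0	0
GLU	HA	H	0	0	0
GLY	N	N	0	1	0
GLY	CA	C	0	0	0
GLY	C	C	0	0	0
GLY	O	O	0	0	1
GLY	OXT	O	0	0	1
GLY	H	H	0	0	0
GLY	HA	H	0	0	0
HIS	N	N	0	1	0
HIS	CA	C	0	0	0
HIS	C	C	0	0	0
HIS	O	O	0	0	1
HIS	OXT	O	0	0	1
HIS	CB	C	0	0	0
HIS	CG	C	0	0	0
HIS	ND1	N	0	1	1
HIS	CD2	C	0	0	0
HIS	CE1	C	0	0	0
HIS	NE2	N	0	1	1
HIS	H	H	0	0	0
HIS	HA	H	0	0	0
HIS	HD1	H	0	0	0
HIS	HE2	H	0	0	0
ILE	N	N	0	1	0
ILE	CA	C	0	0	0
ILE	C	C	0	0	0
ILE	O	O	0	0	1
ILE	OXT	O	0	0	1
ILE	CB	C	0	0	0
ILE	CG1	C	0	0	0
ILE	CG2	C	0	0	0
ILE	CD1	C	0	0	0
ILE	H	H	0	0	0
ILE	HA	H	0	0	0
LEU	N	N	0	1	0
LEU	CA	C	0	0	0
LEU	C	C	0	0	0
LEU	O	O	0	0	1
LEU	OXT	O	0	0	1
LEU	CB	C	0	0	0
LEU	CG	C	0	0	0
LEU	CD1	C	0	0	0
LEU	CD2	C	0	0	0
LEU	H	H	0	0	0
LEU	HA	H	0	0	0
LYS	N	N	0	1	0
LYS	CA	C	0	0	0
LYS	C	C	0	0	0
LYS	O	O	0	0	1
LYS	OXT	O	0	0	1
LYS	CB	C	0	0	0
LYS	CG	C	0	0	0
LYS	CD	C	0	0	0
LYS	CE	C	0	0	0
LYS	NZ	N	1	1	0
LYS	H	H	0	0	0
LYS	HA	H	0	0	0
LYS	HZ1	H	0	0	0
LYS	HZ2	H	0	0	0
LYS	HZ3	H	0	0	0
MET	N	N	0	1	0
MET	CA	C	0	0	0
MET	C	C	0	0	0
MET	O	O	0	0	1
MET	OXT	O	0	0	1
MET	CB	C	0	0	0
MET	CG	C	0	0	0
MET	SD	S	0	0	1
MET	CE	C	0	0	0
MET	H	H	0	0	0
MET	HA	H	0	0	0
PHE	N	N	0	1	0
PHE	CA	C	0	0	0
PHE	C	C	0	0	0
PHE	O	O	0	0	1
PHE	OXT	O	0	0	1
PHE	CB	C	0	0	0
PHE	CG	C	0	0	0
PHE	CD1	C	0	0	0
PHE	CD2	C	0	0	0
PHE	CE1	C	0	0	0
PHE	CE2	C	0	0	0
PHE	CZ	C	0	0	0
PHE	H	H	0	0	0
PHE	HA	H	0	0	0
PRO	N	N	0	0	0
PRO	CA	C	0	0	0
PRO	C	C	0	0	0
PRO	O	O	0	0	1
PRO	OXT	O	0	0	1
PRO	CB	C	0	0	0
PRO	CG	C	0	0	0
PRO	CD	C	0	0	0
PRO	H	H	0	0	0
PRO	HA	H	0	0	0
SER	N	N	0	1	0
SER	CA	C	0	0	0
SER	C	C	0	0	0
SER	O	O	0	0	1
SER	OXT	O	0	0	1
SER	CB	C	0	0	0
SER	OG	O	0	1	1
SER	H	H	0	0	0
SER	HA	H	0	0	0
SER	HG	H	0	0	0
THR	N	N	0	1	0
THR	CA	C	0	0	0
THR	C	C	0	0	0
THR	O	O	0	0	1
THR	OXT	O	0	0	1
THR	CB	C	0	0	0
THR	OG1	O	0	1	1
THR	CG2	C	0	0	0
THR	H	H	0	0	0
THR	HA	H	0	0	0
THR	HG1	H	0	0	0
TRP	N	N	0	1	0
TRP	CA	C	0	0	0
TRP	C	C	0	0	0
TRP	O	O	0	0	1
TRP	OXT	O	0	0	1
TRP	CB	C	0	0	0
TRP	CG	C	0	0	0
TRP	CD1	C	0	0	0
TRP	CD2	C	0	0	0
TRP	NE1	N	0	1	0
TRP	CE2	C	0	0	0
TRP	CE3	C	0	0	0
TRP	CZ2	C	0	0	0
TRP	CZ3	C	0	0	0
TRP	CH2	C	0	0	0
TRP	H	H	0	0	0
TRP	HA	H	0	0	0
TRP	HE1	H	0	0	0
TYR	N	N	0	1	0
TYR	CA	C	0	0	0
TYR	C	C	0	0	0
TYR	O	O	0	0	1
TYR	OXT	O	0	0	1
TYR	CB	C	0	0	0
TYR	CG	C	0	0	0
TYR	CD1	C	0	0	0
TYR	CD2	C	0	0	0
TYR	CE1	C	0	0	0
TYR	CE2	C	0	0	0
TYR	CZ	C	0	0	0
TYR	OH	O	0	1	1
TYR	H	H	0	0	0
TYR	HA	H	0	0	0
TYR	HH	H	0	0	0
VAL	N	N	0	1	0
VAL	CA	C	0	0	0
VAL	C	C	0	0	0
VAL	O	O	0	0	1
VAL	OXT	O	0	0	1
VAL	CB	C	0	0	0
VAL	CG1	C	0	0	0
VAL	CG2	C	0	0	0
VAL	H	H	0	0	0
VAL	HA	H	0	0	0
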