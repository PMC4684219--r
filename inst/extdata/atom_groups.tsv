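# Atom typing table: 10 groups (0..9).
#   0 C_c   carbon with no covalent bond to O/N (resolved from the bond graph)
#   1 C_on  carbon covalently bonded to O or N   (resolved from the bond graph)
#   2 Nd    neutral hydrogen-bond donor nitrogen
#   3 Nc    charged donor nitrogen (LYS NZ, ARG guanidinium)
#   4 Oa    carbonyl/amide acceptor oxygen
#   5 Oc    carboxylate oxygen (and C-terminal OXT)
#   6 Oh    hydroxyl oxygen (donor and acceptor)
#   7 S     sulfur
#   8 PI    aromatic-ring pseudo-atom (assigned in code)
#   9 W     water oxygen
# res_name "*" is a fallback over all standard residues; group "C" defers a
# carbon to C_c/C_on classification from covalent topology. This table is a
# reconstruction anchored on the published contact-group semantics; edit to
# taste.
res_name	atom_name	group
*	N	2
*	CA	C
*	C	C
*	O	4
*	OXT	5
*	CB	C
ARG	NE	3
ARG	NH1	3
ARG	NH2	3
ASN	OD1	4
ASN	ND2	2
ASP	OD1	5
ASP	OD2	5
CYS	SG	7
GLN	OE1	4
GLN	NE2	2
GLU	OE1	5
GLU	OE2	5
HIS	ND1	2
HIS	NE2	2
LYS	NZ	3
MET	SD	7
SER	OG	6
THR	OG1	6
TRP	NE1	2
TYR	OH	6
HOH	O	9
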