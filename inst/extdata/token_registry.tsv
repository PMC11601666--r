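token	smiles	source
A	C[C@@H](N)C(=O)O	L-alanine, free amino acid
R	N=C(N)NCCC[C@@H](N)C(=O)O	L-arginine, free amino acid, neutral guanidine
N	NC(=O)C[C@@H](N)C(=O)O	L-asparagine, free amino acid
D	OC(=O)C[C@@H](N)C(=O)O	L-aspartate, free amino acid, neutral
C	SC[C@@H](N)C(=O)O	L-cysteine, free amino acid
E	OC(=O)CC[C@@H](N)C(=O)O	L-glutamate, free amino acid, neutral
Q	NC(=O)CC[C@@H](N)C(=O)O	L-glutamine, free amino acid
G	NCC(=O)O	glycine, free amino acid
H	N[C@@H](Cc1c[nH]cn1)C(=O)O	L-histidine, free amino acid, neutral tau tautomer
I	CC[C@H](C)[C@@H](N)C(=O)O	L-isoleucine, free amino acid
L	CC(C)C[C@@H](N)C(=O)O	L-leucine, free amino acid
K	NCCCC[C@@H](N)C(=O)O	L-lysine, free amino acid, neutral
M	CSCC[C@@H](N)C(=O)O	L-methionine, free amino acid
F	N[C@@H](Cc1ccccc1)C(=O)O	L-phenylalanine, free amino acid
P	OC(=O)[C@@H]1CCCN1	L-proline, free amino acid
S	OC[C@@H](N)C(=O)O	L-serine, free amino acid
T	C[C@H](O)[C@@H](N)C(=O)O	L-threonine, free amino acid
W	N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O	L-tryptophan, free amino acid
Y	N[C@@H](Cc1ccc(O)cc1)C(=O)O	L-tyrosine, free amino acid
V	CC(C)[C@@H](N)C(=O)O	L-valine, free amino acid
S-PHOS	N[C@@H](COP(=O)(O)O)C(=O)O	O-phosphoserine
T-PHOS	C[C@H](OP(=O)(O)O)[C@@H](N)C(=O)O	O-phosphothreonine
Y-PHOS	N[C@@H](Cc1ccc(OP(=O)(O)O)cc1)C(=O)O	O-phosphotyrosine
R-CIT	NC(=O)NCCC[C@@H](N)C(=O)O	citrulline (deiminated arginine)
P-HYP	O[C@H]1C[C@@H](C(=O)O)NC1	trans-4-hydroxyproline
K-ME1	CNCCCC[C@@H](N)C(=O)O	N6-methyllysine
K-ME2	CN(C)CCCC[C@@H](N)C(=O)O	N6,N6-dimethyllysine
K-ME3	C[N+](C)(C)CCCC[C@@H](N)C(=O)O	N6,N6,N6-trimethyllysine (cationic)
K-AC	CC(=O)NCCCC[C@@H](N)C(=O)O	N6-acetyllysine
K-FOR	O=CNCCCC[C@@H](N)C(=O)O	N6-formyllysine
K-OH	NC[C@H](O)CC[C@@H](N)C(=O)O	5-hydroxylysine
Y-NO2	N[C@@H](Cc1ccc(O)c([N+](=O)[O-])c1)C(=O)O	3-nitrotyrosine
Y-SO3	N[C@@H](Cc1ccc(OS(=O)(=O)O)cc1)C(=O)O	O-sulfotyrosine
E-CGL	OC(=O)C(C(=O)O)C[C@@H](N)C(=O)O	gamma-carboxyglutamate
E-ME	COC(=O)CC[C@@H](N)C(=O)O	glutamate 5-methyl ester
D-ME	COC(=O)C[C@@H](N)C(=O)O	aspartate 4-methyl ester
R-ME1	CNC(=N)NCCC[C@@H](N)C(=O)O	omega-N-methylarginine
R-ME2	CN(C)C(=N)NCCC[C@@H](N)C(=O)O	asymmetric omega-N,N-dimethylarginine
M-OX	CS(=O)CC[C@@H](N)C(=O)O	methionine sulfoxide
C-CAM	NC(=O)CSC[C@@H](N)C(=O)O	S-carbamidomethylcysteine
C-SO3	N[C@@H](CS(=O)(=O)O)C(=O)O	cysteic acid
C-ME	CSC[C@@H](N)C(=O)O	S-methylcysteine
W-OH	N[C@@H](Cc1c[nH]c2ccc(O)cc12)C(=O)O	5-hydroxytryptophan
H-ME1	Cn1cnc(C[C@@H](N)C(=O)O)c1	N1-methylhistidine
Q-PYR	O=C1CC[C@H](C(=O)O)N1	pyroglutamate (cyclized glutamine)
A-AIB	CC(C)(N)C(=O)O	2-aminoisobutyrate (alpha-methylalanine)
G-NME	CNCC(=O)O	sarcosine (N-methylglycine)
F-NH2	N[C@@H](Cc1ccc(N)cc1)C(=O)O	4-aminophenylalanine
F-FLU	N[C@@H](Cc1ccc(F)cc1)C(=O)O	4-fluorophenylalanine
L-NLE	CCCC[C@@H](N)C(=O)O	norleucine
V-NVA	CCC[C@@H](N)C(=O)O	norvaline
S-AC	CC(=O)OC[C@@H](N)C(=O)O	O-acetylserine
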