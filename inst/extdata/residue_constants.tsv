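# Average residue masses: Expasy ProtParam documentation (free amino acid, Da);
# atom counts from free amino-acid molecular formulas (C,H,N,O,S). In-chain residue = free - H2O.
residue	mass_free	atoms_free
A	89.0932	13
C	121.1582	14
D	133.1027	16
E	147.1293	19
F	165.1891	23
G	75.0666	10
H	155.1546	20
I	131.1729	22
K	146.1876	24
L	131.1729	22
M	149.2113	20
N	132.1179	17
P	115.1305	17
Q	146.1445	20
R	174.201	26
S	105.0926	14
T	119.1192	17
V	117.1463	19
W	204.2252	27
Y	181.1885	24
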