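# Functional-group definition table: 82 named SMARTS patterns.
# Columns: name<TAB>smarts. Lines starting with '#' are comments.
name	smarts
hydroxyl	[OX2H]
primary alcohol	[CX4H2][OX2H]
secondary alcohol	[CX4H1]([#6])[OX2H]
tertiary alcohol	[CX4]([#6])([#6])([#6])[OX2H]
phenol	[OX2H][c]
carbonyl	[CX3]=[OX1]
aldehyde	[CX3H1](=O)[#6]
ketone	[#6][CX3](=O)[#6]
carboxyl	[CX3](=O)[OX2H1]
carboalkoxy	[#6][CX3](=O)[OX2H0][#6]
ether	[OD2]([#6])[#6]
methoxy	[OX2][CH3]
peroxide	[OX2][OX2]
primary amine	[NX3H2][CX4]
secondary amine	[NX3H1;!$(NC=O);!$(NS=O)]([#6])[#6]
tertiary amine	[NX3H0;!$(NC=O);!$(NS=O);!$(N=O)]([#6])([#6])[#6]
quaternary ammonium	[NX4+]
aromatic amine	[NX3][c]
amide	[NX3][CX3](=[OX1])
nitrile	[NX1]#[CX2]
nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
nitroso	[NX2]=[OX1]
azo	[#6][NX2]=[NX2][#6]
azide	[$([NX2]=[NX2+]=[NX1-]),$([NX1-][NX2+]#[NX1])]
hydrazine	[NX3][NX3]
hydrazone	[NX3][NX2]=[CX3]
imine	[CX3]=[NX2]
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
thiol	[SX2H]
thioether	[SX2]([#6])[#6]
disulfide	[SX2][SX2]
sulfoxide	[SX3](=[OX1])([#6])[#6]
sulfone	[SX4](=[OX1])(=[OX1])([#6])[#6]
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
sulfonic acid	[SX4](=O)(=O)[OX2H]
sulfate	[SX4](=O)(=O)([OX2])[OX2]
thiocarbonyl	[CX3]=[SX1]
thioamide	[NX3][CX3]=[SX1]
phosphate	[PX4](=[OX1])([OX2])([OX2])[OX2]
phosphonate	[PX4](=[OX1])([OX2])[#6]
phosphine	[PX3]([#6])([#6])[#6]
fluoro	[F][#6]
chloro	[Cl][#6]
bromo	[Br][#6]
iodo	[I][#6]
trifluoromethyl	[CX4](F)(F)F
acyl halide	[CX3](=[OX1])[F,Cl,Br,I]
anhydride	[CX3](=O)[OX2][CX3](=O)
carbamate	[NX3][CX3](=[OX1])[OX2H0]
urea	[NX3][CX3](=[OX1])[NX3]
guanidine	[NX3][CX3](=[NX2])[NX3]
amidine	[NX3][CX3]=[NX2]
enol	[OX2H][CX3]=[CX3]
enamine	[NX3][CX3]=[CX3]
epoxide	[OX2r3]1[#6r3][#6r3]1
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
allene	[CX3]=[CX2]=[CX3]
phenyl	c1ccccc1
benzyl	[CX4H2]c1ccccc1
methyl	[CX4H3]
alkyl chain	[CX4H2][CX4H2]
acetal	[CX4H0,CX4H1]([OX2H0])[OX2H0]
hemiacetal	[CX4]([OX2H])[OX2H0][#6]
furan	c1ccoc1
thiophene	c1ccsc1
pyrrole	c1cc[nH]c1
pyridine	c1ccncc1
imidazole	c1cnc[nH]1
pyrazole	c1cc[nH]n1
oxazole	c1ocnc1
thiazole	c1scnc1
pyrimidine	c1cncnc1
pyrazine	c1cnccn1
indole	c1ccc2[nH]ccc2c1
quinoline	n1ccc2ccccc2c1
naphthalene	c1ccc2ccccc2c1
piperidine	[NX3H1]1[CX4][CX4][CX4][CX4][CX4]1
piperazine	N1CCNCC1
morpholine	O1CCNCC1
pyrrolidine	[NX3H1]1[CX4][CX4][CX4][CX4]1
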