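# Curated fixture corpus of drug-like and enumerated small molecules.
# One canonical SMILES per line.
CC(=O)Oc1ccccc1C(=O)O
CC(=O)Nc1ccc(O)cc1
CC(C)Cc1ccc(C(C)C(=O)O)cc1
Cn1c(=O)c2c(ncn2C)n(C)c1=O
CN1CCC[C@H]1c1cccnc1
NC(=O)c1ccc[nH]1
OC[C@@H](O)[C@H](O)[C@@H](O)CO
NCCc1ccc(O)c(O)c1
CC(N)Cc1ccccc1
O=C(O)c1ccccc1O
Clc1ccccc1Cl
Nc1ccc(S(N)(=O)=O)cc1
CCOC(=O)c1ccccc1N
OCC1OC(O)C(O)C(O)C1O
CC(=O)OCC1OC(OC(C)=O)C(OC(C)=O)C1OC(C)=O
NC(Cc1ccccc1)C(=O)O
NC(CO)C(=O)O
NC(CS)C(=O)O
CSCCC(N)C(=O)O
O=C(O)CC(O)(CC(=O)O)C(=O)O
OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1
CN(C)CCC=C1c2ccccc2CCc2ccccc21
COc1ccc2cc(C(C)C(=O)O)ccc2c1
OCCOCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
CN1C2CCC1CC(OC(=O)C(CO)c1ccccc1)C2
O=C(O)c1cc(O)c(O)c(O)c1
Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2
C1CCC(N2CCCCC2)CC1
CC(C)(C)c1ccc(O)cc1
CCN(CC)CCNC(=O)c1ccc(N)cc1
COc1cc(C=CC(=O)O)ccc1O
C=CCc1ccc(O)c(OC)c1
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O
NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O
CCCCCC(O)C=CC1C(O)CC(=O)C1CC=CCCCC(=O)O
Nc1ncnc2[nH]cnc12
O=c1[nH]c(=O)c2[nH]cnc2[nH]1
Cc1ccc(S(=O)(=O)NC(=O)NN2CCCCC2)cc1
CC(=O)SC1CC2=CC(=O)CCC2(C)C2CCC3(C)C(CCC3(C)O)C12
CCC(C)C1(CC)C(=O)NC(=O)NC1=O
CN1CCCC1CCO
COC(=O)c1ccccc1O
O=C(Cc1ccccc1)NCCc1ccc(O)cc1
CC(C)=CCCC(C)=CCO
CC1CCC(C(C)C)C(O)C1
CC(=O)C1CCC2C3CCC4CC(O)CCC4(C)C3CCC12C
O=C1CCCCC1
OC1CCCCC1
C1COCCO1
CN(C)C(=N)N=C(N)N
OCC(O)CO
CC(O)C(O)C(O)CO
CCCCCCCCCC(=O)O
CCCCCCCCO
CC=CC=CC(=O)O
NC(N)=O
NC(N)=S
CC(NC(=O)OC(C)(C)C)C(=O)O
CSSC
CCS(=O)CC
CCS(=O)(=O)CC
c1ccc2c(c1)oc1ccccc12
c1ccc2c(c1)sc1ccccc12
c1ccc2c(c1)[nH]c1ccccc12
c1ccc2ncccc2c1
CC1=CC(=O)CC(C)(C)C1
c1ccc(C2CC2)cc1
CNCC1CCCCC1
Brc1cccnc1
OCC1CCCNC1
NC1CCCNC1
O=C(Oc1ccc(Cl)cc1)c1ccccc1
O=S(=O)(Nc1ccncc1)c1ccccc1
Clc1ccc(COc2ccccc2)cc1
O=C(Oc1ccc(O)cc1)c1ccccc1
c1ccc(CCC2CCCCC2)cc1
C#CC1CCCNC1
Clc1ccc(OCc2ccccc2)cc1
Fc1ccc2ccccc2c1
O=CNc1cccnc1
O=C(NC1CCCCC1)c1ccccc1
CNCC1CCCNC1
Oc1ccc(NCc2ccccc2)cc1
CCOc1cccnc1
BrC1CCCNC1
CNc1ccc2ccccc2c1
Clc1ccc(NCc2ccccc2)cc1
CNCc1cccnc1
c1ccc(OCC2CCNCC2)cc1
O=C(Nc1ccncc1)c1ccccc1
SCC1CCCNC1
O=CNCC1CCCCC1
SCC1CCCCC1
Sc1cccnc1
O=CNCc1ccc2ccccc2c1
c1ccc(COC2CCCCC2)cc1
FC1CCCNC1
COC1CCCNC1
O=C(Nc1ccccc1)C1CCCCC1
BrC1CCCCC1
SCc1cccnc1
O=C(Oc1ccccc1)c1ccncc1
O=C(Nc1ccccc1)c1ccc(Cl)cc1
O=CNC1CCCCC1
Oc1ccc(CCc2ccccc2)cc1
O=C(CO)Oc1cccnc1
Sc1ccc2ccccc2c1
O=COc1cccnc1
SCc1ccc2ccccc2c1
Clc1ccc2ccccc2c1
Nc1cccnc1
O=COc1ccc2ccccc2c1
c1ccc(CNc2ccncc2)cc1
OCc1ccc2ccccc2c1
CNc1cccnc1
COc1cccnc1
IC1CCCNC1
C=CC1CCCCC1
O=C(CO)OC1CCCNC1
Clc1cccnc1
Oc1ccc2ccccc2c1
Oc1ccc(COc2ccccc2)cc1
c1ccc(CNC2CCCCC2)cc1
CNC1CCCNC1
SC1CCCCC1
c1ccc(CCC2CCNCC2)cc1
O=S(=O)(Nc1ccc(Cl)cc1)c1ccccc1
O=C(OC1CCCCC1)c1ccccc1
Brc1ccc2ccccc2c1
O=C(CO)Oc1ccc2ccccc2c1
COc1ccc2ccccc2c1
Oc1ccc(OCc2ccccc2)cc1
SC1CCCNC1
c1ccc(OCc2ccncc2)cc1
C#Cc1ccc2ccccc2c1
Nc1ccc2ccccc2c1
O=C(Nc1ccccc1)c1ccc(O)cc1
NC1CCCCC1
c1ccc(COc2ccncc2)cc1
O=CNC1CCCNC1
OCc1cccnc1
O=S(=O)(NC1CCNCC1)c1ccccc1
FC1CCCCC1
O=C(Oc1ccccc1)C1CCCCC1
C#CC1CCCCC1
O=C(OC1CCNCC1)c1ccccc1
O=CNCC1CCCNC1
CCOC1CCCCC1
O=C(Oc1ccccc1)C1CCNCC1
Fc1cccnc1
O=C(Nc1ccccc1)c1ccncc1
O=C(Oc1ccccc1)c1ccc(Cl)cc1
ClC1CCCNC1
O=S(=O)(NC1CCCCC1)c1ccccc1
Clc1ccc(CCc2ccccc2)cc1
Ic1ccc2ccccc2c1
O=C(Nc1ccc(O)cc1)c1ccccc1
O=CNCc1cccnc1
O=C(Oc1ccccc1)c1ccc(O)cc1
O=COC1CCCCC1
c1ccc(CNC2CCNCC2)cc1
O=S(=O)(Nc1ccc(O)cc1)c1ccccc1
CNC1CCCCC1
O=COCC1CCCNC1
IC1CCCCC1
O=COCc1cccnc1
CNCc1ccc2ccccc2c1
COC1CCCCC1
O=COCC1CCCCC1
C=CC1CCCNC1
c1ccc(COC2CCNCC2)cc1
c1ccc(OCC2CCCCC2)cc1
Oc1cccnc1
c1ccc(CCc2ccncc2)cc1
OC1CCCNC1
O=COCc1ccc2ccccc2c1
O=C(Nc1ccc(Cl)cc1)c1ccccc1
O=C(NC1CCNCC1)c1ccccc1
O=C(Nc1ccccc1)C1CCNCC1
C#Cc1cccnc1
O=C(Oc1ccncc1)c1ccccc1
O=C(NCc1ccccc1)c1ccsc1
c1ccc(COCc2ccsc2)cc1
Nc1ccc(OC(=O)c2ccccc2)cc1
FC1COCCN1
O=C(Cc1ccccc1)Nc1ccncc1
O=C(Nc1cc[nH]c1)c1ccccc1
O=S(=O)(Nc1ccc(CO)cc1)c1ccccc1
O=C(Oc1ccoc1)c1ccccc1
O=C(Cc1ccccc1)NC1CCNCC1
O=C(Oc1ccccc1)c1ccoc1
Nc1cncnc1
COc1cncnc1
Nc1ccc2[nH]ccc2c1
COc1ccc2[nH]ccc2c1
OCc1ccc(NCc2ccccc2)cc1
O=C(NCc1ccccc1)c1ccncc1
O=C(NCc1ccccc1)c1cc[nH]c1
O=COc1ccc2[nH]ccc2c1
Oc1ccc2[nH]ccc2c1
Nc1ccc(COCc2ccccc2)cc1
OCc1ccc(COCc2ccccc2)cc1
c1ccc(COCC2CCNCC2)cc1
Nc1ccc(NC(=O)c2ccccc2)cc1
Nc1ccc(NCc2ccccc2)cc1
c1ccc(CNc2ccoc2)cc1
O=C(Nc1ccccc1)c1ccc(CO)cc1
c1ccc(CNc2cc[nH]c2)cc1
Fc1cncnc1
Nc1ccc(C(=O)Nc2ccccc2)cc1
O=COC1COCCN1
Nc1ccc(C(=O)NCc2ccccc2)cc1
c1ccc(COCc2cc[nH]c2)cc1
O=C(Nc1ccsc1)c1ccccc1
COC1COCCN1
O=C(Nc1ccccc1)c1ccoc1
Clc1ccc2[nH]ccc2c1
CCN(C)Cc1cncnc1
O=C(Oc1cc[nH]c1)c1ccccc1
Nc1ccc(NC(=O)Cc2ccccc2)cc1
O=C(Oc1ccccc1)c1cc[nH]c1
ClC1CCOC1
O=C(Nc1ccccc1)c1ccsc1
NC1CCOC1
O=C(NCc1ccccc1)c1ccc(CO)cc1
O=COc1cncnc1
Oc1cncnc1
O=COCc1cncnc1
CCN(C)Cc1ccc2[nH]ccc2c1
O=S(=O)(Nc1ccoc1)c1ccccc1
NC1COCCN1
CCN(C)CC1CCOC1
Clc1cncnc1
O=C(Nc1ccccc1)c1cc[nH]c1
O=C(Oc1ccccc1)c1ccc(CO)cc1
O=COCC1CCOC1
O=C(Nc1ccoc1)c1ccccc1
O=[SH](=O)Nc1cncnc1
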