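compound_id,smiles
aspirin,CC(=O)Oc1ccccc1C(=O)O
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
paracetamol,CC(=O)Nc1ccc(O)cc1
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O
naproxen,COc1ccc2cc(ccc2c1)C(C)C(=O)O
curcumin,COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O
tamoxifen,CC/C(=C(\c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1
quercetin,O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12
genistein,O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12
econazole,Clc1ccc(COC(Cn2ccnc2)c2ccc(Cl)cc2Cl)cc1
miconazole,Clc1ccc(COC(Cn2ccnc2)c2ccc(Cl)cc2Cl)c(Cl)c1
clotrimazole,Clc1ccccc1C(c1ccccc1)(c1ccccc1)n1ccnc1
ketoconazole,CC(=O)N1CCN(c2ccc(OCC3COC(Cn4ccnc4)(c4ccc(Cl)cc4Cl)O3)cc2)CC1
amiodarone,CCCCc1oc2ccccc2c1C(=O)c1cc(I)c(OCCN(CC)CC)c(I)c1
diazepam,CN1c2ccc(Cl)cc2C(=Nc2ccccc21)c1ccccc1
diclofenac,O=C(O)Cc1ccccc1Nc1c(Cl)cccc1Cl
warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
propranolol,CC(C)NCC(O)COc1cccc2ccccc12
metoprolol,COCCc1ccc(OCC(O)CNC(C)C)cc1
sertraline,CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21
fluoxetine,CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1
imatinib,Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1
gefitinib,COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1
erlotinib,COCCOc1cc2ncnc(Nc3cccc(C#C)c3)c2cc1OCCOC
sorafenib,CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1
sunitinib,CCN(CC)CCNC(=O)c1c(C)[nH]c(/C=C2\C(=O)Nc3ccc(F)cc32)c1C
dasatinib,Cc1nc(Nc2ncc(C(=O)Nc3c(C)cccc3Cl)s2)cc(N2CCN(CCO)CC2)n1
lapatinib,CS(=O)(=O)CCNCc1ccc(-c2ccc3ncnc(Nc4ccc(OCc5cccc(F)c5)c(Cl)c4)c3c2)o1
sildenafil,CCCc1nn(C)c2c(=O)[nH]c(-c3cc(S(=O)(=O)N4CCN(C)CC4)ccc3OCC)nc12
simvastatin,CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21
atorvastatin,CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O
losartan,CCCCc1nc(Cl)c(CO)n1Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1
valsartan,CCCCC(=O)N(Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1)C(C(C)C)C(=O)O
omeprazole,COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1
ranitidine,CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1
cimetidine,CC1=C(CSCCNC(=NC)NC#N)NC=N1
morphine,CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5
codeine,COc1ccc2CC3C4C=CC(O)C5Oc1c2C45CCN3C
nicotine,CN1CCCC1c1cccnc1
chloroquine,CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12
haloperidol,O=C(CCCN1CCC(O)(c2ccc(Cl)cc2)CC1)c1ccc(F)cc1
risperidone,Cc1nc2CCCCn2c(=O)c1CCN1CCC(c2noc3cc(F)ccc23)CC1
olanzapine,CN1CCN(C2=Nc3cc(C)ccc3Nc3sc(C)cc32)CC1
clozapine,CN1CCN(C2=Nc3cc(Cl)ccc3Nc3ccccc32)CC1
methotrexate,CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc1
penicillin_g,CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O
ciprofloxacin,O=C(O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O
doxycycline,CC1c2cccc(O)c2C(O)=C2C(=O)C3(O)C(O)=C(C(N)=O)C(=O)C(N(C)C)C3C(O)C12
levodopa,NC(Cc1ccc(O)c(O)c1)C(=O)O
melatonin,COc1ccc2[nH]cc(CCNC(C)=O)c2c1
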