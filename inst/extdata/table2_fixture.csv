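protein,protein_utf8,is_phospho,p_mean,dir_mean,p_s1,dir_s1,p_s2,dir_s2,p_s3,dir_s3
4E-BP1,4E-BP1,0,0.000,+,0.001,+,0.002,+,0.001,+
EGFR,EGFR,0,0.000,+,0.005,+,0.004,+,0.001,+
HER2,HER2,0,0.000,+,0.000,+,0.002,+,0.000,+
pB-Raf,pB-Raf,1,0.000,-,0.026,+,0.000,+,0.001,+
pPTEN,pPTEN,1,0.000,+,0.008,+,0.004,+,0.002,+
pS6RP,pS6RP,1,0.003,+,0.005,+,0.002,+,0.000,+
pVEGFR,pVEGFR,1,0.006,-,0.003,+,0.009,+,0.004,+
VEGF,VEGF,0,0.000,+,0.000,+,0.000,+,0.004,+
VEGFR,VEGFR,0,0.001,-,0.002,-,0.003,-,0.000,-
VHL,VHL,0,0.006,+,0.000,+,0.000,+,0.000,+
pHER2,pHER2,1,n.s.,,0.001,+,0.000,+,0.000,+
PI3K,PI3K,0,n.s.,,0.026,+,0.004,-,0.005,+
AKT,AKT,0,0.030,+,n.s.,,0.006,+,n.s.,
pAKT,pAKT,1,0.018,-,0.000,,n.s.,,n.s.,
Angiopoietin2,Angiopoietin2,0,0.000,+,n.s.,,n.s.,,n.s.,
B-Raf,B-Raf,0,0.000,-,n.s.,,n.s.,,0.042,+
p1068EGFR,p1068EGFR,1,0.000,-,n.s.,,n.s.,,0.049,+
p1148EGFR,p1148EGFR,1,0.000,+,n.s.,,n.s.,,n.s.,
FAK,FAK,0,0.000,+,n.s.,,n.s.,,n.s.,
GSK3b,GSK3β,0,n.s.,,n.s.,,n.s.,,n.s.,
pGSK3b,pGSK3β,1,0.000,+,0.036,+,0.021,+,n.s.,
Hif-1a,Hif-1α,0,0.000,-,n.s.,,n.s.,,n.s.,
JNK/SAPK,JNK/SAPK,0,0.000,+,n.s.,,n.s.,,0.021,+
mTOR,mTOR,0,0.000,+,n.s.,,n.s.,,n.s.,
pmTOR,pmTOR,1,0.000,-,n.s.,,n.s.,,n.s.,
p4E-BP1,p4E-BP1,1,n.s.,,n.s.,,n.s.,,n.s.,
p38 MAPK,p38 MAPK,0,0.000,+,n.s.,,n.s.,,0.003,+
pp38 MAPK,pp38 MAPK,1,n.s.,,n.s.,,n.s.,,n.s.,
ERK,ERK,0,n.s.,,n.s.,,n.s.,,n.s.,
pERK,pERK,1,n.s.,,n.s.,,n.s.,,n.s.,
pPRAS40,pPRAS40,1,0.000,-,n.s.,,n.s.,,n.s.,
PTEN,PTEN,0,0.010,+,n.s.,,n.s.,,n.s.,
pPDGFR,pPDGFR,1,0.003,-,0.026,+,n.s.,,0.018,+
PDGF,PDGF,0,0.042,-,n.s.,,n.s.,,n.s.,
S6RP,S6RP,0,0.000,+,n.s.,,n.s.,,n.s.,
PRAS40,PRAS40,0,0.002,+,n.s.,,n.s.,,n.s.,
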