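ENG
NT5E
THY1
CD44
MCAM
VCAM1
ICAM1
NGFR
PDGFRA
PDGFRB
ITGB1
ITGA1
ITGA2
ITGA5
CD9
CD63
CD81
CD151
F3
PDPN
CD164
DPP4
MME
ALCAM
CD34
PTPRC
CD14
ITGAM
CD79A
CD19
HLA-DRA
HLA-DRB1
CD36
CXCR4
KIT
PROM1
CD99
CD46
CD55
CD59
CD47
SLC3A2
TNFRSF1A
IL6R
CD109
BST1
CD248
CD200
THBD
ANPEP
ITGAV
ITGB5
CD40
CD70
TFRC
FAS
CD27
CD38
CD53
CD58
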