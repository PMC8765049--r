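PDCD1
CTLA4
LAG3
HAVCR2
TIGIT
BTLA
CD160
CD244
ENTPD1
ITGAE
TOX
TOX2
EOMES
BATF
IRF4
NR4A1
NR4A2
NR4A3
VSIR
KLRG1
CD38
CD27
TNFRSF9
TNFRSF18
TNFRSF4
ICOS
CD200R1
PRDM1
MAF
ID2
ID3
TBX21
STAT3
CXCL13
CCL3
CCL4
CCL4L2
IFNG
GZMB
FASLG
TNFSF9
IL10
IL21
RAB27A
SIRPG
SNAP47
PHLDA1
DUSP4
CD82
AKAP5
TNS3
CXCR6
CCR8
MYO7A
PTMS
FUT8
FABP5
GBP2
GBP5
WARS1
UBE2L6
LYST
TNFRSF1B
CASP8
ITM2A
CD63
LGALS1
LGALS3
PRDX3
PKM
ENO1
LDHA
HLA-DRA
HLA-DRB1
CD74
PSMB9
TAP1
STAT1
IFI35
ISG15
MX1
OASL
APOBEC3G
APOBEC3C
CHST12
GALM
TPI1
SIT1
UCP2
B2M
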