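symbol
SEPT1
SEPT2
SEPT3
SEPT4
SEPT5
SEPT6
SEPT7
SEPT8
SEPT9
SEPT10
SEPT11
SEPT12
SEPT13
SEPT14
SEP15
MARCH1
MARCH2
MARCH3
MARCH4
MARCH5
MARCH6
MARCH7
MARCH8
MARCH9
MARCH10
MARCH11
DEC1
DEC2
OCT1
OCT4
APR3
AGO1
AGO2
AGO3
AGO4
MEI1
TAMM41
jun-1
2310009E13
1110059E24
2610009E16
TP53
NCF1
INF2
BRCA1
BRCA2
EGFR
KRAS
NRAS
HRAS
MYC
MYCN
ALK
RET
MET
KIT
FLT3
JAK2
STAT3
STAT1
AKT1
AKT2
PIK3CA
PTEN
RB1
CDKN2A
CDK4
CDK6
CCND1
VEGFA
FGFR1
FGFR2
FGFR3
ERBB2
ERBB3
NOTCH1
NOTCH2
WNT1
CTNNB1
APC
SMAD4
TGFB1
GAPDH
ACTB
TUBB
VIM
CDH1
CDH2
EPCAM
KRT18
KRT19
MKI67
PCNA
TOP2A
AURKA
AURKB
PLK1
BUB1
MAD2L1
CENPA
CENPE
KIF11
ESR1
ESR2
PGR
AR
GATA3
FOXA1
FOXP3
SOX2
SOX9
NANOG
KLF4
LIN28A
POU5F1
SALL4
ZIC2
PAX6
PAX3
MITF
TYR
PMEL
MLANA
CD4
CD8A
CD19
MS4A1
CD34
PTPRC
ITGAM
ITGAX
NCAM1
KLRD1
GZMB
PRF1
IFNG
TNF
IL2
IL4
IL6
IL10
IL17A
CXCL8
CCL2
CCR5
CXCR4
TLR4
MYD88
NFKB1
RELA
IKBKB
MAPK1
MAPK3
MAPK8
MAP2K1
RAF1
BRAF
SRC
ABL1
BCR
HBB
HBA1
ALB
APOE
APOB
LDLR
PCSK9
CETP
LPL
INS
INSR
IGF1
IGF1R
GH1
GHR
LEP
LEPR
ADIPOQ
PPARG
SREBF1
FASN
ACACA
CPT1A
HMGCR
CYP3A4
CYP2D6
CYP1A1
GSTM1
GSTP1
NAT2
UGT1A1
ABCB1
ABCC1
ABCG2
SLC2A1
SLC6A4
DRD2
HTR2A
COMT
MAOA
BDNF
NTRK2
NGF
GDNF
SNCA
PARK7
PINK1
PRKN
LRRK2
MAPT
APP
PSEN1
PSEN2
HTT
FMR1
MECP2
DMD
CFTR
F8
F9
VWF
G6PD
PAH
HEXA
GBA
SMN1
SMN2
TERT
TERC
DKC1
XRCC1
XRCC5
ERCC1
MSH2
MLH1
PMS2
ATM
ATR
CHEK1
CHEK2
MDM2
BAX
BCL2
CASP3
CASP8
CASP9
FAS
FASLG
BID
BAK1
MCL1
XIAP
BIRC5
HIF1A
EPAS1
VHL
EPO
EPOR
SLC4A1
JUN
JUNB
JUND
FOS
FOSB
EGR1
KLF2
SP1
YY1
E2F1
MARCKS
SEPW1
DECR1
NOVA1
AUGN
FEB
MAYP
SEPSECS
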