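TP53
RB1
EGFR
CREBBP
LRP1B
KMT2D
PTEN
MYC
MYCN
PIK3CA
KRAS
STK11
KEAP1
NOTCH1
NOTCH2
FAT1
ARID1A
ARID2
SMARCA4
BRCA1
BRCA2
ATM
ATR
APC
ALK
BRAF
CDKN2A
ERBB2
FGFR1
NFE2L2
PTPRD
SOX2
TERT
CD274
EP300
NF1
CDKN1A
FBXW7
SETD2
KMT2C
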