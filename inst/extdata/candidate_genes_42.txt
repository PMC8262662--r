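BMP4
CTNNB1
ESCO2
FGF10
FGF2
FGF8
HAND2
RBM8A
RECQL4
SALL4
SHH
TBX5
TP53
TP63
WNT1
WNT3A
CRBN
CUL4A
DDB1
DTL
IKZF1
IKZF3
MEIS2
RBX1
ABCB1
ABCB4
CYP1A1
CYP1A2
CYP2C19
CYP3A4
CYP3A5
CDH5
KDR
NOS2
NOS3
VEGFA
DKK1
GSS
GSTP1
NFKB1
NFKB2
TNF
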