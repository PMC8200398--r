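peptide	hpepdock_score
PEW	-157.801
VSVGF	-157.768
PSQK	-152.549
TTPW	-145.896
ATSF	-137.604
ITY	-126.941
TSF	-123.304
DISF	-113.395
VY	-112.665
SW	-111.589
VASL	-110.73
TF	-103.79
DSSTK	-101.083
VPN	-100.335
IL	-95.602
VETN	-94.906
GEPTL	-94.454
DW	-93.887
SF	-93.527
SVL	-92.453
QR	-92.11
PK	-91.866
AF	-91.54
AF	-91.54
SIK	-89.499
SIK	-89.499
IR	-89.461
DPR	-89
SSL	-87.756
ETN	-87.603
AH	-85.115
DR	-82.929
GR	-82.866
ER	-81.692
DF	-78.98
ASK	-78.633
TN	-77.845
DTL	-77.331
GGL	-72.523
VN	-71.853
GN	-63.773
DN	-62.512
AL	-61.361
GL	-53.133
DL	-50.735
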