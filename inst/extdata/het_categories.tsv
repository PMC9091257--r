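het_code	category
CLR	steroid
CHS	steroid
Y01	steroid
CHD	steroid
ERG	steroid
OLA	fatty_acid
OLB	fatty_acid
OLC	fatty_acid
PLM	fatty_acid
MYR	fatty_acid
STE	fatty_acid
PAM	fatty_acid
ELA	fatty_acid
PEG	polymer
PGE	polymer
PG4	polymer
P6G	polymer
1PE	polymer
P33	polymer
PPG	polymer
7PE	polymer
PE4	polymer
SO4	anion
PO4	anion
CL	anion
NO3	anion
BR	anion
IOD	anion
ACT	anion
CIT	anion
BOG	surfactant
LMT	surfactant
BNG	surfactant
DDM	surfactant
LDA	surfactant
UDM	surfactant
HTG	surfactant
OGA	surfactant
MAL	surfactant
LPP	surfactant
MHA	surfactant
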