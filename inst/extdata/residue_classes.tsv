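aa	class
A	apolar
V	apolar
L	apolar
I	apolar
M	apolar
G	apolar
P	apolar
C	apolar
F	aromatic
W	aromatic
Y	aromatic
S	polar
T	polar
N	polar
Q	polar
K	positive
R	positive
H	positive
D	negative
E	negative
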