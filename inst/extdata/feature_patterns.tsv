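feature_class	smarts
donor	[#7,#8;!H0]
acceptor	[#7,#8;v2,v3;!$([N+]);!$([O+])]
aromatic	[a]
halogen	[F,Cl,Br,I]
basic	[NX3;!$(NC=O);!$(N~[!#6;!#1])]
acidic	[CX3](=O)[OX1H0-,OX2H1]
aliphatic_ring	[C;R]
everything	[*]
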