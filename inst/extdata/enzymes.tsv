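name	recognition
SacI	GAGCTC
XhoI	CTCGAG
PstI	CTGCAG
KpnI	GGTACC
SapI	GCTCTTC
Mva1269I	GAATGC
EcoRI	GAATTC
NcoI	CCATGG
NotI	GCGGCCGC
BamHI	GGATCC
HindIII	AAGCTT
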