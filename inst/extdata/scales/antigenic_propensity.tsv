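residue	value
A	1.064
R	0.873
N	0.776
D	0.866
C	1.412
Q	1.015
E	0.851
G	0.874
H	1.105
I	1.152
L	1.250
K	0.930
M	0.826
F	1.091
P	1.064
S	1.012
T	0.909
W	0.893
Y	1.161
V	1.383
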