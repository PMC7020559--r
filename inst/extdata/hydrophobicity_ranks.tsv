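residue	rank
A	14
C	16
D	3
E	4
F	17
G	13
H	7
I	20
K	2
L	18
M	15
N	5
P	8
Q	6
R	1
S	11
T	12
V	19
W	10
Y	9
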