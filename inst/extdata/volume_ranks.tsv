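residue	rank
A	2
C	4
D	5
E	9
F	18
G	1
H	12
I	14
K	16
L	15
M	13
N	7
P	6
Q	11
R	17
S	3
T	8
V	10
W	20
Y	19
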