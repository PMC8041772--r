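aa	a	d	e
A	0.6	1.0	1.0
C	0.4	0.4	0.4
D	0.0	0.3	0.3
E	0.0	0.3	0.3
F	1.0	0.5	0.5
G	0.0	0.0	0.0
H	0.3	0.8	0.8
I	1.5	0.8	0.8
K	0.1	0.3	0.3
L	2.0	1.0	1.0
M	1.2	0.8	0.8
N	0.2	1.0	1.0
P	-4.0	-4.0	-4.0
Q	0.2	0.8	0.8
R	0.1	0.3	0.3
S	0.2	1.0	1.0
T	0.3	0.8	0.8
V	1.2	0.8	0.8
W	0.8	0.4	0.4
X	0.0	0.0	0.0
Y	0.6	0.4	0.4
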