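element	radius	eps	rmin
C	1.87	0.1	4
N	1.65	0.2	3.6
O	1.4	0.15	3.4
S	1.85	0.45	4
H	1	0.03	1.6
P	1.9	0.2	4.2
X	1.8	0.1	4
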