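gene	s1	s2
g1	5.2	1.1
g2	3.4	4.8
g3	2.9	2.9
g4	1.7	6.3
g5	0.6	0.2
g6	4.1	3.5
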