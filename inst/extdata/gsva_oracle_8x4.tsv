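gene	s1	s2	s3	s4
g1	7.1	2.3	5.5	4.0
g2	1.2	6.6	3.3	2.8
g3	4.4	4.4	4.4	6.1
g4	0.9	1.8	7.7	0.4
g5	5.8	3.1	2.2	5.2
g6	2.6	5.9	6.8	1.5
g7	3.7	0.5	1.0	7.3
g8	6.3	7.2	0.6	3.9
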