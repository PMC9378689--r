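# Idealized planar nucleobase heavy-atom templates (Angstrom).
# Curated data: MMFF94-optimized N-methyl nucleobases flattened onto the
# ring least-squares plane; frame: glycosidic N (N1/N9) at origin, C1'
# stub on +x at 1.47 A, ring neighbour (C8/C6) at +y.
base	atom	x	y
A	C1'	1.4700	0.0000
A	N9	0.0000	-0.0000
A	C8	-0.8149	1.0983
A	N7	-2.0891	0.7637
A	C5	-2.0898	-0.6183
A	C4	-0.7948	-1.1111
A	N3	-0.4118	-2.3982
A	C2	-1.4858	-3.2142
A	N1	-2.7958	-2.8813
A	C6	-3.1241	-1.5690
A	N6	-4.4712	-1.2286
G	C1'	1.4700	0.0000
G	N9	0.0000	0.0000
G	C8	-0.8147	1.1020
G	N7	-2.0915	0.7721
G	C5	-2.0869	-0.6006
G	C4	-0.8044	-1.1015
G	N3	-0.4056	-2.3959
G	C2	-1.4026	-3.2392
G	N2	-1.1592	-4.5744
G	N1	-2.7310	-2.8633
G	C6	-3.1790	-1.5487
G	O6	-4.3744	-1.2717
C	C1'	1.4700	0.0000
C	N1	0.0000	-0.0000
C	C6	-0.6682	1.2011
C	C5	-1.9987	1.2457
C	C4	-2.6838	-0.0613
C	N4	-4.0509	-0.1076
C	N3	-2.0590	-1.1959
C	C2	-0.6835	-1.2216
C	O2	-0.0777	-2.2910
U	C1'	1.4700	0.0000
U	N1	0.0000	-0.0000
U	C6	-0.6615	1.2106
U	C5	-1.9936	1.2873
U	C4	-2.7759	0.0413
U	O4	-4.0007	0.0652
U	N3	-2.0517	-1.1143
U	C2	-0.6836	-1.2112
U	O2	-0.1446	-2.3154
T	C1'	1.4700	0.0000
T	N1	0.0000	-0.0000
T	C6	-0.6610	1.2110
T	C5	-1.9964	1.3011
T	C7	-2.7575	2.5853
T	C4	-2.7769	0.0412
T	O4	-4.0032	0.0388
T	N3	-2.0485	-1.1126
T	C2	-0.6822	-1.2095
T	O2	-0.1433	-2.3138
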