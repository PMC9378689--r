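# van der Waals radii (Angstrom), Bondi (1964) set with common extensions
# for metals seen in RNAP depositions; element symbols upper-case.
element	radius
H	1.20
C	1.70
N	1.55
O	1.52
P	1.80
S	1.80
SE	1.90
F	1.47
CL	1.75
BR	1.85
I	1.98
ZN	1.39
MG	1.73
NA	2.27
K	2.75
CA	2.31
MN	1.61
FE	1.61
NI	1.63
CU	1.40
CO	1.61
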