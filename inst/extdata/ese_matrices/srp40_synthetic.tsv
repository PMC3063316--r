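# matrix: SRp40
# SYNTHETIC placeholder weights: motif width and threshold follow the
# published ESEfinder values for this SR protein, but the per-position
# weights are generated stand-ins. Replace with the published matrix
# for real annotation work; package tests never rely on these values.
threshold	2.67
A	C	G	T
-0.21	1.05	-2.7	-1.93
0.73	-1.14	-2.53	1.09
0.55	-0.57	-1.4	1.35
0.79	-0.49	-1.53	0.12
-2.13	-2.97	-2.62	1.19
-2.58	-0.43	0.7	0.62
-2.51	0.75	0.81	0.76
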