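# matrix: SRp55
# SYNTHETIC placeholder weights: motif width and threshold follow the
# published ESEfinder values for this SR protein, but the per-position
# weights are generated stand-ins. Replace with the published matrix
# for real annotation work; package tests never rely on these values.
threshold	2.676
A	C	G	T
1.05	0.23	-0.87	0.6
-1.86	-1.91	0.69	0.17
0.84	-1.59	-0.88	-1.84
0.93	-0.35	1.05	-1.59
0.73	-1.45	-1.12	-2.67
-0.92	0.44	-2.56	1.23
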