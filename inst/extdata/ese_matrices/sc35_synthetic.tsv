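# matrix: SC35
# SYNTHETIC placeholder weights: motif width and threshold follow the
# published ESEfinder values for this SR protein, but the per-position
# weights are generated stand-ins. Replace with the published matrix
# for real annotation work; package tests never rely on these values.
threshold	2.383
A	C	G	T
1.27	0.22	-0.48	-2.5
1.18	-0.96	1.25	-0.48
-1.57	-2.57	0.67	-0.75
-0.91	0.76	0.29	-1.63
-1.02	1.22	-0.83	-0.73
0.76	1.17	-0.81	-0.46
-2.72	-2.08	1.03	0.68
-2.28	1.16	-0.45	-1.41
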