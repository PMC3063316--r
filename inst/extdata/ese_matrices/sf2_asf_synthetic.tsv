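# matrix: SF2/ASF
# SYNTHETIC placeholder weights: motif width and threshold follow the
# published ESEfinder values for this SR protein, but the per-position
# weights are generated stand-ins. Replace with the published matrix
# for real annotation work; package tests never rely on these values.
threshold	1.956
A	C	G	T
-2.04	0.78	-0.06	-0.21
-2.23	1	0.84	-1.01
-1.32	-0.23	1.3	-1.92
-2.93	0.7	0.62	1.15
1.21	-2.17	-2.53	-2.67
-1.65	-1.73	1.07	-0.32
-0.8	1.14	-1.12	0.94
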