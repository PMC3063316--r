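# Exonic splicing silencer hexamers, FAS-hex-3 style.
# PARTIAL SET: only the four hexamers relevant to the bundled examples are
# included; replace this file with the full published FAS-hex-3 list for
# real annotation work.
GGGAGG
TAGGTA
TTAGGT
CTTAGG
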