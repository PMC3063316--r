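annotation	category
brain	brain
brain tumor	brain
glioblastoma	brain
ovary	ovary
ovarian carcinoma	ovary
tonsill	tonsil
tonsil	tonsil
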