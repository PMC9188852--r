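pattern	match	category
up-regulates	prefix	1
down-regulates	prefix	2
form complex	exact	3
unknown	exact	3
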