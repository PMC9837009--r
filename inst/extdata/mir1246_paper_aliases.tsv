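internal_id	published_id	label
7	5	A14C
11	6	G15C
12	7	G15U
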