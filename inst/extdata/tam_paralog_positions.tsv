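pos	ref	tyro3	mer
48	R	N	N
56	E	E	Q
70	E	Q	L
73	D	D	H
83	E	-	D
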