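method	pos	letter
sdppred	46	T
sdppred	48	R
sdppred	50	Q
sdppred	84	D
sdppred	96	K
multirelief	48	R
multirelief	70	E
harmony	46	T
harmony	48	R
harmony	50	Q
harmony	96	K
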