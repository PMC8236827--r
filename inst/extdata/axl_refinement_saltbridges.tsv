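sb	axl_res	ligand_res
SB1	48	460
SB2	56	308
SB3	59	310
SB4	70	414
SB5	73	313
SB6	83	467
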