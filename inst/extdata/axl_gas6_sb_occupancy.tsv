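sb	axl_res	gas6_res	replica1	replica2	replica3	replica4
SB4	70	414	81.14	34.57	55.41	70.57
SB5	73	313	72.86	81.71	69.43	76.86
SB6	83	467	60.29	48.00	68.57	71.14
SB3	59	310	59.43	32.86	83.14	56.86
SB1	48	455	43.71	44.00	53.43	30.57
SB2	56	308	NA	NA	NA	25.14
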