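sb	axl_res	pros1_res	replica1	replica2	replica3	replica4
SB3	59	314	97.67	97.67	94.33	94.33
SB2	59	316	NA	NA	NA	66.66
SB1	48	465	64.67	51.67	NA	33.00
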