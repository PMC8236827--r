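# Per-residue interaction energies after water refinement (kcal/mol)
# chain resno resid E_vdw E_elec E_total
A 48 ARG -2.10 -45.30 -47.40
A 56 GLU -1.75 -38.20 -39.95
A 59 GLU -2.40 -41.10 -43.50
B 414 ARG -1.90 -36.70 -38.60
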