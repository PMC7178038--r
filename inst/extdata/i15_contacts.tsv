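# Published shortest side-chain proton-proton contact distances (angstrom)
# between the central packing residue I15 of the hyperthermophilic ACP and
# its eight hydrophobic partners, as printed in the structure report.
partner	distance_A
V11	2.1
L19	2.1
V26	3.1
L32	2.1
L36	2.4
L46	2.1
F50	2.4
V69	3.1
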