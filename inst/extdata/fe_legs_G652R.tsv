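# Published free-energy differences of the transmembrane thermodynamic
# cycle for the G652R substitution (kJ/mol); same conventions as the
# L658Q table.
process	state	value	uncertainty
ins	wt	0	0
ins	mutant	-18.4	0
N-dimer	wt	0	0
N-dimer	mutant	5.9	0
C-dimer	wt	0	0
C-dimer	mutant	2.8	0
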