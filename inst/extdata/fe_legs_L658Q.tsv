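# Published free-energy differences of the transmembrane thermodynamic
# cycle for the L658Q substitution (kJ/mol). Only mutation-induced
# differences are printed, so wild-type legs are set to zero by convention
# and mutant legs carry the ddG values; no uncertainties were published.
process	state	value	uncertainty
ins	wt	0	0
ins	mutant	39.8	0
N-dimer	wt	0	0
N-dimer	mutant	-0.2	0
C-dimer	wt	0	0
C-dimer	mutant	-49.2	0
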