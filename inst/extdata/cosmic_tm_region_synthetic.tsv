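# Synthetic catalogue extract for the transmembrane-neighborhood scan
# (P631-L683 window, precursor numbering). Contains the two hydrophilic
# membrane-central substitutions plus decoys exercising each exclusion
# rule: near-edge hydrophilic (I646T, V651D, G663R), hydrophobic central
# (L657F, M650V, F667L), and outside-helix (R669Q, I673T) substitutions.
protein_change	occurrence_count
G652R	2
L658Q	1
I646T	1
M650V	1
V651D	1
L657F	1
G663R	1
F667L	1
R669Q	1
I673T	1
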