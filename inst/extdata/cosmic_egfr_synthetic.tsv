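# Synthetic stand-in for a somatic-mutation catalogue extract of the
# receptor gene: protein-level substitutions with at-least-once occurrence.
# Occurrence counts are plausible placeholders, not database exports;
# the membership filter only requires presence with count >= 1.
protein_change	occurrence_count
L858R	2000
T790M	600
L861Q	100
G719S	50
S768I	40
A289V	20
G652R	2
S442I	2
L658Q	1
L927L	1
H1129Y	1
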