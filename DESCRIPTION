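Package: pfseq
Title: Deep Mutational Scanning Enrichment, Flow Quantitation, and
    Transmembrane Energetics for Receptor Activation Screens
Version: 0.1.0
Authors@R:
    person("pfseq", "developers", email = "pfseq@example.org",
           role = c("aut", "cre"))
Description: Desk-scale re-implementation of a PhosphoFlowSeq-style screen
    for constitutively activating receptor tyrosine kinase mutations.
    Provides generators for single-nucleotide-variant libraries under
    activity-dependent flow-sorting selection with sequencing and PCR-artifact
    noise, two-channel flow-cytometry events, Crooks-consistent nonequilibrium
    work samples, and idealized transmembrane helix-dimer trajectories;
    the three-filter enrichment pipeline (frequency, fold-enrichment versus a
    loss-of-function reference, catalogue membership) used to nominate
    activating mutations from count tables; geometric-mean fluorescence
    quantitation with background subtraction, wild-type normalization and
    paired t-tests; a Kyte-Doolittle hydropathy scan for hydrophilic
    membrane-central candidate mutations and GxxxG-type motif detection;
    Jarzynski and Crooks-Gaussian-intersection free-energy estimators with
    thermodynamic-cycle assembly and closure checks; and trajectory
    observables (inter-motif minimum distances, residue contact-distance
    maps, hydrogen-bond occupancy) from multi-MODEL PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
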