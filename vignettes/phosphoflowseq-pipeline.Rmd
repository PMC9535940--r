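---
title: "Models and design choices of the pfseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices of the pfseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfseq)
```

# What the package models

`pfseq` is a desk-scale re-implementation of the computational side of a
PhosphoFlowSeq screen: a randomly mutated receptor tyrosine kinase library is
expressed in cells, cells with ligand-independent receptor phosphorylation
are flow-sorted, recovered plasmids are re-amplified and deep-sequenced, and
per-variant read counts are filtered to nominate activating mutations. The
wet-lab stages (transfection, staining, sorting, sequencing chemistry) are
replaced by a generative simulator with known ground truth; everything
downstream of the count tables is implemented as it would be run on real
data. Two companion analyses are included: a Kyte-Doolittle hydropathy scan
that nominates hydrophilic, membrane-central catalogue mutations, and a
nonequilibrium free-energy toolbox (Jarzynski and Crooks-Gaussian
estimators, thermodynamic-cycle assembly) with geometric trajectory
observables for transmembrane helix dimers.

# The selection simulator

`enumerate_snv_library()` builds the exhaustive single-substitution library:
three alternative bases at each position, so a 3630-nt coding sequence gives
10890 variants. Ground-truth activities (wild type = 1) are planted with
`assign_activities()`; the default benchmark set
(`default_activating_map()`) places the five confirmed activating protein
changes S442I, L658Q, S768I, T790M, L858R at activity 5, a level consistent
with the strong constitutive phosphorylation these mutations show relative
to unstimulated wild type.

Selection is modeled as a per-round multiplicative enrichment factor
`activity^s` with `s = -log(gate_stringency)`. The sorting experiments are
not quantitatively characterized in terms of per-round enrichment, so this
is a deliberate modeling choice: it is monotone in activity, neutral at
stringency 1, and makes the stringency parameter interpretable (the
fraction of cells sorted). The default stringency 0.05 corresponds to a
tight sort gate (s = 3: an activity-5 variant gains 125-fold per round).
The loss-of-function reference selection uses the inverse exponent,
favoring inactive variants. Frequencies propagate deterministically between
rounds (the sort and plasmid-recovery bottlenecks are not resampled);
stochasticity enters through per-position multinomial read sampling at
`depth_per_round` coverage, which dominates at the depths used here.

The unselected library assigns each variant the same molecule frequency
with a total mutant fraction of 0.7 — roughly one mutation per clone on
average for an error-prone PCR library, i.e. a realistic single-mutant
regime. Multi-mutant molecules are out of scope; counts are treated as
pre-attributed per site, matching short-read per-nucleotide calling.

PCR artifacts (`apply_pcr_noise()`) reassign reads from the wild-type pool
of each position to substitution artifacts at a per-substitution rate, with
the C-to-T rate multiplied by `ct_bias_factor`. Reassignment (rather than
adding reads) conserves coverage, matching how artifact reads displace true
reads at fixed sequencing depth. The bias is applied to the coding strand
only by default (`mirror_ga = TRUE` extends it to G-to-A); the direction of
the bias is documented for the amplification step, its strandedness is not.
The default rates (1.2e-3 per substitution, bias 10) put C-to-T artifacts
at about 1.2% frequency — above the 1% frequency filter but flat across
selections — which reproduces the situation the fold-enrichment filter
exists to solve: artifacts pass filter 1 and are removed by filter 2
because they accumulate independently of selection pressure.

# The three-filter pipeline

Frequencies are exact ratios of variant count to per-position coverage in
the same condition (no smoothing; the denominator follows per-nucleotide
variant calling, not total library reads). The filters are:

1. frequency strictly above 1% in at least one activation-selected
   experiment (OR across experiments A and B, because hits are reported
   per experiment — per-experiment flags are kept in the report);
2. strictly more than 8-fold the loss-of-function reference frequency;
   with several reference libraries the maximum (most conservative)
   reference frequency is used, and a zero reference frequency is replaced
   by the pseudofrequency `0.5 / coverage`, which avoids infinite ratios
   while preserving ordering;
3. membership in a somatic-mutation catalogue, tested on protein-level
   labels including synonymous notation (`L927L`), since the published hit
   list mixes missense and synonymous changes.

The final verdict is the intersection, so filter order is irrelevant.
Thresholds are strict inequalities throughout; a variant at exactly 1% or
exactly 8-fold is excluded.

# Flow-cytometry model and quantitation

Wild-type phospho signal follows a piecewise log-linear curve of
expression: proportional below a knee, log-log slope 2 above it, emulating
the super-linear ("exponential") ligand-independent activation of the
wild-type receptor at high surface densities. The knee is an *absolute*
expression level (default: the 80th percentile of the default expression
distribution, about 2300 a.u.) because the density at which
ligand-independent dimerization sets in is a property of the receptor, not
of the transfection: shifting the expression distribution moves cells
across the knee rather than moving the knee. Activating variants multiply
the specific signal uniformly across expression levels, matching the
observation that mutant activation is seen across a broad expression
range. Multiplicative log-normal noise (sd 0.35 on the natural log) and an
additive log-normal background floor (median 5 a.u., the nontransfected
signal) complete the model; background is kept well below the wild-type
specific signal (median 200 a.u. at typical expression), as in a
well-compensated phospho stain, which is why geometric-mean statistics
recover planted activities to within a few percent.

Quantitation mirrors the published procedure: gate receptor-expressing
cells (gates operate in log10 space, half-open and lower-inclusive; events
with non-positive signals are dropped with a message, since geometric
statistics need positivity), compute the geometric mean fluorescence
intensity of the phospho channel, subtract the nontransfected background,
normalize to unstimulated wild type, then aggregate replicates as mean and
SD — normalization before aggregation. The paired t-test is two-tailed and
uncorrected, as in the original analysis; degenerate inputs follow the
conventions `t = 0, p = 1` (all differences zero) and `p = 0` (zero
variance, nonzero mean). Diagonal gates (slope/intercept in log10-log10
space) de-bias sorting against highly expressing wild-type cells; their
instrument settings are not published, so gates are always user-supplied
configuration. Bead calibration fits `log10(molecules)` on
`log10(intensity)` by least squares.

# Hydropathy scan

The scan uses the standard 20-entry Kyte-Doolittle index. "Hydrophilic"
means strictly below 0, the conventional midpoint: it cleanly separates
the catalogue candidates (Gln -3.5, Arg -4.5) from the transmembrane
wild-type residues, of which only the small residues Gly (-0.4) and Thr
(-0.7) sit marginally below zero. The membrane-center rule keeps positions
strictly more than `margin = 5` residues from both helix ends, because
hydrophilic side chains near the membrane surface can snorkel toward the
lipid head groups. The helix boundary itself (default I646-M668) is not
stated alongside the published rule, so it is exposed as configuration
with this documented default; the scan window P631-L683 matches the
published figure. Motif detection generalizes GxxxG to
small-x-x-x-small with a configurable small-residue set (default G, A, S,
T; the motifs of this helix use G, A, T), and reports overlapping hits
offset by one as the double pattern small-small-x-x-small-small (TGMVGA).

# Free-energy estimators and the thermodynamic cycle

Work samples are stored with the convention that `reverse` is the work of
the reverse transformation; the Crooks comparison negates it internally.
The Jarzynski estimate uses a log-sum-exp formulation for overflow safety.
The Crooks-Gaussian intersection fits Gaussians by sample moments (simple,
and faithful to the method's spirit; no bias-corrected ML), uses the
closed-form midpoint for equal variances, and otherwise takes the
quadratic root between the two fitted means — the physically meaningful
crossing — while reporting both roots. `kT` defaults to 2.577 kJ/mol
(310 K, the simulation temperature); the generator produces
Crooks-consistent Gaussian work (forward mean `dG + sigma^2/2kT`), so both
estimators converge to the planted `dG` and their agreement is a testable
invariant.

Recomputing the published insertion/dimerization free energies would
require alchemical molecular dynamics in lipid bilayers and is explicitly
out of scope. The cycle module instead consumes leg tables. Because only
mutation-induced differences are published, the packaged leg fixtures set
wild-type legs to zero and carry the differences on the mutant legs; the
pose-change difference then follows by arithmetic,
`ddG_pose = ddG_Cdimer - ddG_Ndimer`. Closure is checked generally: legs
are edges of a graph over (environment, variant) states, a spanning forest
assigns potentials, and each remaining leg closes one independent loop
whose signed sum is reported as a residual (zero for any consistent
state-energy assignment). Uncertainties, when present, propagate in
quadrature; the published values carry none, so fixtures default to zero.

# Helix-dimer fixtures and trajectory observables

The dimer generator builds two ideal alpha-helices (rise 0.15 nm/residue,
100 degrees/residue, heavy atoms only: backbone N/CA/C/O, CB, and a full
Gln side chain where present) over the 30-residue K642-R671 segment in
precursor numbering, with the database-sequence residues M650 and M668.
The chains cross at a configurable angle, with the crossing point pinned
at a side-chain-bearing residue of the contact motif (M650 for the N-pose
TGMVGA contact, I664 for the C-pose ALGIG contact) so that facing CB atoms
realize an inter-motif minimum distance near 0.45 nm while the other motif
stays beyond 1 nm. Chain B is the exact two-fold image of chain A about
the dimer axis (per-frame jitter is mirrored), which makes contact maps
chain-swap symmetric by construction — a property the tests exploit.
Hydrogen-bond frames are deterministic: the leading
`round(fraction * n_frames)` frames place the Gln-658 amide pseudo-atoms
on the interface so the geometric criterion holds exactly, giving exact
occupancy; in all other frames the side chain points away from the
interface. These are geometric fixtures, not physics: side-chain internal
geometry in bonded frames is deliberately not realistic, and no membrane
or solvent exists. A green trajectory test therefore establishes that the
observables are computed correctly, not that the poses are thermodynamically
meaningful.

Observables: the inter-motif minimum distance is the per-frame minimum
heavy-atom distance between the two spans; the contact map entry (i, j) is
the frame-mean of the per-frame minimum heavy-atom distance between
residue i of chain A and j of chain B ("contact distance" is not formally
defined in the source analysis; a Calpha variant is available by flag).
The hydrogen-bond criterion without explicit hydrogens is donor-acceptor
distance <= 0.35 nm plus the acceptor within a 30-degree cone of the
antecedent-to-donor direction; with hydrogens, D-H...A >= 150 degrees.
Both are common MD-analysis conventions and fully configurable. Frames are
equally weighted; no time unit is attached. Trajectories are exchanged as
multi-MODEL PDB (Angstrom on disk, nm in memory; round trips are exact to
PDB precision, 0.001 Angstrom).

# What the synthetic world does and does not establish

The generators emulate: exhaustive single-substitution diversity,
activity-monotone enrichment over two selection rounds, multinomial
sequencing noise at realistic coverage, C-to-T-biased amplification
artifacts, two-channel flow events with the super-linear wild-type
expression dependence, Crooks-consistent Gaussian work, and pose-specific
dimer geometry. They do not emulate: multi-mutant clones, indels (the
published screens could not recover exon-19 deletions either), sort and
plasmid-recovery bottleneck drift, base-quality or alignment error,
spectral compensation, or any membrane physics. Green recovery tests
therefore establish that the pipeline's statistics are implemented
correctly and that its filters behave as designed under the stated noise
model — not that the screen would perform identically on real libraries.

# Worked example

```{r example}
lib <- assign_activities(enumerate_snv_library(synthetic_egfr_cds(1)),
                         default_activating_map())
cfg <- selection_config(depth_per_round = 1e5, seed = 3,
                        pcr_error_rate = 1.2e-3)
tab <- simulate_screen(lib, cfg)
cosmic <- read_cosmic_fixture(pfseq_example("cosmic_egfr_synthetic.tsv"))
report <- run_filter_pipeline(tab, cosmic, c("actA_r2", "actB_r2"), "lof_r2")
print(report)

cycle <- assemble_cycle(
  read_free_energy_legs(pfseq_example("fe_legs_L658Q.tsv")))
print(cycle)
```

# Numerical conventions

* All filter thresholds are strict inequalities; gates are half-open,
  lower-inclusive, in log10 space.
* Seeds: every generator takes an explicit seed and is bit-reproducible
  under it; composite simulations derive sub-seeds by fixed small offsets.
* Degenerate inputs: zero coverage with nonzero counts is a
  data-integrity error; empty gate results are allowed and flagged; an
  empty count table yields a coverage-QC report flagged invalid.
* Units: frequencies are fractions, energies kJ/mol, coordinates nm,
  flow signals arbitrary units, positions 1-based precursor numbering.
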