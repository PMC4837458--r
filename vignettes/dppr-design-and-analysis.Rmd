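---
title: "Designer PPR proteins: code-programmed RNA recognition, structure geometry and binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designer PPR proteins: code-programmed RNA recognition, structure geometry and binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprkit)
```

## The model

Pentatricopeptide repeat (PPR) proteins read single-stranded RNA one
nucleotide per repeat. Each repeat is a degenerate 35-residue helical
hairpin; natural proteins carry tandem arrays of 2–30 of them. Within a
repeat, the amino-acid pair at internal positions 5 and 35 — the PPR
code — determines which base the repeat accepts at the Watson–Crick
face. The canonical design codes are ND → U, NS → C, SN → A and TD → G;
the degenerate codes NN (U or C), TN (A) and SD (G) follow from the
same recognition chemistry. Position 5 is the chief determinant:
asparagine correlates with pyrimidines (its amide donates a hydrogen
bond to the pyrimidine O2), serine or threonine with purines (their
hydroxyl donates to the purine N3). Position 35 refines the choice
directly for purines (one bond to adenine N1, two to guanine N1/N2) and
through a bridging water for pyrimidines, whose polarity — uracil N3
donates, cytosine N3 accepts — separates U from C.

`pprkit` turns this into four connected capabilities: programming
designer (dPPR) constructs for arbitrary targets, the inverse problem of
predicting targets from repeat arrays, geometric and contact analysis of
solved complexes, and equilibrium binding quantitation.

## The code table

`default_code_table()` stores the seven literature codes as explicit
base-probability profiles and everything else as position-5 fallbacks.
The experimental characterization of the codes is qualitative
(a code "specifically recognizes" its base, or shows "similar
selectivity" to two), so the probability mass is a package choice:
exact codes put 0.90 on their specified base set (split equally when
degenerate, so NN is 0.45/0.45 over U/C), the remainder spread uniformly.
0.90 keeps every argmax unambiguous while leaving the soft scores usable
for transcript scanning; it is configurable both programmatically and
through the plain-text table format of `load_code_table()`. The
small-residue fallback (A or G at position 5) is fixed at
A = G = 0.30, C = U = 0.20 — a mild purine tilt encoding "accommodates
purines but with little specificity". Codes with no entry and no
applicable fallback score uniform 0.25, an honest uninformative prior.

## Designing constructs

`design_dppr()` reproduces the published construct architecture: an
N-terminal capping domain, one 35-residue repeat per target nucleotide
with only positions 5 and 35 substituted, then a C-terminal cap. Repeat
*i* reads nucleotide *i*, N-to-C matching 5′-to-3′. The packaged
scaffold (`inst/extdata/scaffold_synthetic.txt`) is a synthetic
consensus-style stand-in: the machine-readable source for this package
does not carry the literal repeat or cap sequences, so the shipped data
preserves the architecture that the analyses depend on — template length
35, the Val2 hydrophobic clamp, the Lys13 phosphate anchor, cap lengths
51/49 so that the crystal-construct numbering (repeats at residues
174–523 with `offset = 122`) is reproduced — and is documented as
replaceable via `default_scaffold(path = ...)`. The caps were chosen to
be helical-plausible but deliberately dissimilar from the repeat
template, so the repeat scanner does not call them as repeats.

Targets are validated character by character (errors name the offending
base and position). T is tolerated and mapped to U with a warning, since
DNA-typed input is common. Lengths outside 2–30 warn rather than error:
the bound is the family's natural range, not a hard constraint of the
arithmetic. Of the IUPAC ambiguity codes only Y (pyrimidine) is
accepted, and only under `allow_ambiguity = TRUE`, because NN is the
only degenerate code with direct experimental support for a two-base
specificity.

## The inverse problem

`build_repeat_pssm()` derives a 35 × 20 log2-odds profile from the
scaffold consensus with columns 5 and 35 zeroed — the code slots are
free by construction, so repeat detection is independent of the
programmed specificity. The pseudocount (default 0.5 total mass per
column) tolerates the degeneracy of natural repeats. `scan_protein()`
slides the profile at stride 1, keeps windows above 0.6 of the maximum
attainable score, and chains candidates greedily from the best-scoring
seed at spacing 35 ± 1. The 0.6 threshold is admittedly arbitrary; it is
validated behaviourally — designed constructs of every length 2–30 are
recovered exactly, composition-matched shuffles yield nothing — rather
than calibrated on natural-protein alignments, and natural-PPR
generality is explicitly best-effort. `predict_target()` then maps each
detected repeat's (5,35) pair through the code table into a position
probability matrix, and `scan_transcripts()` scores sense-strand windows
(PPRs bind ssRNA; no reverse complement) as summed log2 odds against a
uniform background, with optional empirical p-values from seeded
mononucleotide shuffles.

## Structure geometry

`read_structure()` parses PDB fixed-column and mmCIF `atom_site`
records, resolving alternate locations to the highest occupancy (ties:
first in file order) and classifying residues as protein, RNA, water or
other. `superpose()` pairs Cα atoms by global sequence alignment
(match 1 / mismatch 0 / gap −1; numbering-based pairing is available as
an option) and computes the closed-form Kabsch least-squares fit,
followed by iterative outlier pruning: pairs deviating more than 2 times
the current RMSD are dropped and the fit repeated, up to 5 cycles. The
published pairwise RMSDs for the four deposited complexes do not state
their protocol; the 2σ × 5 convention is this package's documented
choice, and the acceptance tolerance (±0.15 Å, ±15 retained atoms)
absorbs the ambiguity.

`superhelix()` reduces each repeat to its Cα centroid and fits solenoid
parameters. The axis direction is **not** taken from the principal
component of the centroids: for a solenoid covering roughly one turn —
precisely the deposited geometry, ten repeats at ~36° — centroid PCA is
biased toward the in-plane spread and fails badly. Instead the axis is
the null direction (smallest principal component) of the *second
differences* of consecutive centroids, which on an ideal helix lie
exactly in the plane perpendicular to the axis; the estimate is exact
for ideal helices and least-squares for real ones. The axis position is
then a Kåsa circle fit in the perpendicular plane, giving radius and
centre without the partial-arc bias of using the centroid mean. Rise is
the mean axial spacing, twist the mean signed rotation of the radial
vector (right-handed about the N→C-oriented axis, which is also the
5′→3′ direction of the bound RNA), period = rise × 360/|twist|, and
diameter twice the mean centroid radius. The published "diameter ≈
50 Å" and "polar axis 75 Å" figures for these solenoids are measured
quantities with unstated definitions, so the centroid-based diameter is
the documented convention here and the axis length is not hard-tested.

Hydrogen bonds are called from heavy-atom distance alone (default
3.5 Å, configurable): at 2.2–2.6 Å resolution there are no hydrogens,
so angle terms would be guessed, not measured. This deliberately
over-calls relative to stricter geometric definitions. A water bridge
requires one water oxygen within the cutoff of both the base N3 and a
polar position-35 side-chain atom. Repeat *i* is mapped to the *i*-th
modelled nucleotide in residue order, with a `register_offset` escape
hatch for deposits that differ. `contact_report()` covers the two
non-code interactions the structures emphasize: the Val2 clamp (any
side-chain carbon within 4.5 Å of the aligned or preceding base's ring)
and the Lys13–phosphate salt bridge (NZ within 4.0 Å of a phosphate
oxygen); missing side chains flag the row as incomplete rather than
failing.

## Binding quantitation

The titration model is the protein-excess isotherm
f = [P]ʰ / (Kdʰ + [P]ʰ), valid because the assay's probe (2 nM) sits
well below the dissociation constants of interest (≥ 15 nM); the exact
1:1 quadratic solution is available behind `exact_probe = TRUE` for
completeness. The Hill coefficient is fixed at 1 by default — the
complexes bind as monomers — and can be freed. The fit initializes Kd at
the concentration nearest half-maximal binding, scans a log-spaced grid,
and polishes with a damped 1-D Gauss–Newton iteration; this converges to
machine precision on clean data, where `nls()` notoriously stalls on
zero-residual inputs. Bootstrap intervals use case resampling with a
fixed seed. `simulate_titration()` generates the test world: the
published ten-lane series 0–200 nM, Gaussian noise clipped to [0, 1],
deterministic under seed.

## What the synthetic world does and does not establish

All default tests run on generated fixtures: designed constructs, ideal
superhelices with seeded but mean-centred jitter (so centroid ground
truth stays exact), planted-distance recognition geometries, and
simulated titrations. Green tests establish internal correctness —
round-trip identity, oracle equality against an independent quaternion
superposition, 1% parameter recovery, 10% Kd recovery at the published
noise scale — not agreement with the deposited crystal structures, which
requires fetching the PDB entries (the full coordinate files are too
large to ship as text fixtures). The deposited-structure checks live in
one clearly separated acceptance test and in `fetch_structure()`. The
published Kd values themselves ("∼20–75 nM") derive from gel images that
are not available numerically; the binding module is therefore validated
by parameter recovery, with those values anchoring the simulator's
defaults, not asserted as outputs. Likewise the bootstrap-coverage check
runs at 100 replicates × 250 resamples (scaled down from 200 × 1000 for
suite runtime) with the ≥ 85% criterion unchanged.

## Known limitations

* The repeat PSSM is consensus-derived from the designer scaffold, not
  trained on natural P-type alignments; sensitivity on divergent natural
  repeats is untested.
* The packaged scaffold and caps are synthetic stand-ins (correct
  architecture, not literal natural sequences); designs are
  architecturally faithful but not expression-ready constructs.
* PPM scores are not calibrated to affinity: a mismatch's score drop
  does not translate to a Kd ratio.
* H-bond calls are distance-only; donor/acceptor role assignment is a
  best-effort chemical lookup.
* mmCIF support covers the `atom_site` loop (sufficient for coordinate
  analysis), not the full dictionary.
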