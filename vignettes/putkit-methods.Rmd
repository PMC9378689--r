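---
title: "Methods: quantifying putRNA anti-pausing structure and biochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying putRNA anti-pausing structure and biochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(putkit)
```

## The problem

The HK022 *put* RNA is a nascent-RNA anti-pausing and anti-termination
element: as soon as it is transcribed it folds into a two-stem structure
and docks onto the β′ zinc-binding domain at the RNA exit channel of the
bacterial RNA polymerase elongation complex (EC). Pausing in bacterial RNAP
is associated with *swiveling*, a small rigid-body rotation (a degree to a
few degrees) of a module comprising the clamp, dock, shelf, jaw, SI3 and
the β′ C-terminal region, about an axis roughly parallel to the bridge
helix. A putRNA-bound EC sits in the non-swiveled conformation; a paused,
put-less EC swivels. `putkit` implements the measurements that make this
mechanistic statement quantitative, plus the biochemical readouts used to
validate it (gel-based activity, conservation, native-MS masses).

## Swivel-angle measurement

The measurement is a two-stage superposition:

1. **Core alignment.** The target structure is superposed onto the
   reference with a Kabsch least-squares fit over core-module Cα atoms,
   paired by (chain, residue number, insertion code, atom name). Residues
   missing in either model are dropped symmetrically and the dropped count
   is recorded — deposited models differ in modelled ranges.
2. **Residual swivel rotation.** On the core-aligned target, the
   swivel-module atom set (union of clamp, shelf, jaw, SI3, β′ C-terminal)
   is superposed onto the reference's. The rotation angle of that residual
   transform, `acos((trace(R) - 1) / 2)` computed in the numerically stable
   `atan2` form, is the swivel angle.

The reported scalar is the **full residual rotation angle**, not its
projection onto the bridge-helix axis. The motion is only approximately
axial, and the full angle is the reproducible scalar; the angle between the
residual axis and the bridge-helix axis (principal axis through the
bridge-helix Cα set, oriented N→C) is reported alongside as a diagnostic of
how axial the motion actually was. Per-domain Cα RMSDs after core alignment
are also reported, since domain-wise RMSD tables are the usual companion
statistic.

Assumptions: both modules move as rigid bodies (internal deformation
inflates the fit RMSD but biases the angle only weakly); the core really is
static (the choice of core residues matters more than any numerical
detail). Cα-only fitting is the default because inter-structure comparisons
are conventionally quoted on Cα carbons; `all_backbone` is available.

**Degenerate inputs.** Rotations below 1e-6° have no defined axis
(`rotation_axis` errors; `swivel_angle` reports the angle with NA axis).
Collinear atom sets make the Kabsch problem rank-deficient and are
rejected. The axis sign is fixed by requiring a positive dot product with a
reference direction (bridge helix by default), making reports
deterministic.

**Domain boundaries.** The residue ranges delimiting core and swivel
modules are curated data, not code constants: the packaged
`domains_ecoli.cfg` holds approximate E. coli RNAP ranges from the
swiveling literature, and users are expected to override per structure.
Since published analyses do not print exact boundaries, angles carry an
intrinsic boundary uncertainty of a few tenths of a degree; the synthetic
recovery suite (below) quantifies only the numerical part of the error.

## Surface areas and contacts

Solvent accessibility uses the Shrake–Rupley construction with a
deterministic golden-spiral point set (no RNG — areas are bit-stable),
probe radius 1.4 Å and 960 points per atom by default. 960 points give
better than 1% agreement with the analytic sphere and sub-0.5% change upon
doubling; the cost is linear in points. Radii are the shipped Bondi set
(with metal extensions); the set name is recorded in every report because
buried areas shift by several percent between radii tables.

Buried surface area follows the PISA convention,
`bsa = (SASA(A) + SASA(B) - SASA(A∪B)) / 2`, and interface residues are
those burying more than 0.1 Å² — small enough to be insensitive to point
noise, large enough to exclude numerically zero burials.

Polar contacts use hydrogen-free criteria because cryo-EM depositions at
3–4 Å carry no hydrogens; everything detected is a *potential* contact:

| kind | criterion | default |
|------|-----------|---------|
| hbond | donor–acceptor heavy-atom distance; donor–acceptor–antecedent angle ≥ 90° where a covalent antecedent exists | ≤ 3.5 Å |
| salt bridge | Arg/Lys/His side-chain N to phosphate or carboxylate O; takes priority over hbond on the same atom pair | ≤ 4.0 Å |
| cation-π | side-chain N to base/aromatic ring centroid, centroid→N vector within 30° of the ring normal | ≤ 6.0 Å |

Base substitution (`mutate_base`) replaces base atoms with an idealized
template expressed in the residue's glycosidic frame (glycosidic N origin,
N→C1′ direction, base-plane normal), leaving ribose and phosphate
untouched, then `count_pocket_hbonds` recounts — the in-silico form of the
U28* substitution experiment.

## Base pairs, triplex, hybrid, kink

Candidate pairs must satisfy C1′–C1′ ∈ [7.5, 11.5] Å, inter-base-plane
angle ≤ 35°, and at least one inter-base H bond between edge donor/acceptor
atoms (≤ 3.5 Å). Pairing H bonds are additionally required to lie within
35° of both base planes: without this, stacked neighbours one helical step
apart (rise ≈ 2.8 Å) occasionally present an edge N/O pair under 3.5 Å
whose vector points along the helix axis, producing spurious "pairs".
Residues fewer than 3 positions apart on one chain are not considered.
Selection is greedy — descending H-bond count, then ascending C1′–C1′
distance, then a lexicographic residue key, so ties break deterministically
— and each residue may take at most two partners; the second partner is
flagged `is_triplex_extra`, enough for the put stem I minor-groove triplex.

Saenger classification matches the observed H-bond atom pattern against a
catalog restricted to the classes relevant here: XIX/XX (canonical
Watson–Crick), XXVIII (G·U wobble), VIII (A·G imino), XI (G·A sheared).
A pair matching no entry is `other`; a pattern matching several is
`unassigned`. The full 28-class taxonomy (and the Leontis–Westhof edge
nomenclature) is deliberately out of scope.

The RNA–DNA hybrid is the contiguous run of inter-chain Watson–Crick pairs
ending at the RNA 3′ terminus. The translocation register needs to know
which template base sits at the i+1 site (adjacent to the downstream
duplex); since that is not derivable from a coordinate file alone, callers
supply `downstream_template_resno`, and without it — or with mixed
pre/post populations modelled at partial occupancy — the register is
`ambiguous`.

Kink angles fit a least-squares axis through the C1′ midpoints of each
segment's pairs and report the inter-axis angle folded to [0°, 90°]. Axis
fits through fewer than one helical turn inherit a phase-dependent tilt
from the midpoints' helical arrangement, so segments of at least ~11 pairs
are recommended (the recovery test uses 11 + 11).

## Assay statistic and conservation

Band intensities are calibrated by cytosine count (the label enters via
α-³²P CTP, so intensity is proportional to molar amount × number of C):
`P = (I_p/n_C) / (I_p/n_C + I_r/n_C′)`. The relative anti-pausing activity
`1 − (P_x − P_WT)/(P_put⁻ − P_WT)` is affine-invariant in P and maps WT→1,
put⁻→0 by construction. Activities are deliberately not clipped to [0, 1].
Per-mutant summaries use the replicate's own calibrator lanes, mean ± SEM
(sd/√n), and the 0.2 / 0.9 classification thresholds. Background
subtraction is the caller's responsibility; inputs are assumed corrected.
The quantified time point is carried as a lane attribute, not hardcoded.

Conservation is the identity count to the reference (gaps never match,
case-insensitive), matching the 0–N integer scores painted on structures
from an N-sequence alignment. Computing the alignment itself is out of
scope; aligned FASTA/Clustal/Stockholm are consumed.

## Masses and deconvolution

Transcript masses sum residue masses from an elemental-composition table
(average masses by default — native MS of a 30 kDa RNA resolves average,
not monoisotopic, mass) plus one water and a 5′-end adjustment. The default
5′ end is triphosphate, since in-vitro transcripts initiate with rNTPs; a
switch covers monophosphate and hydroxyl. Proton mass 1.00728 Da; Na⁺/K⁺
adducts are not modelled.

Deconvolution is a deliberate simplification of production tools: assuming
consecutive peaks carry consecutive charges, each candidate charge for the
first peak implies one neutral mass per peak, and the assignment minimising
the spread wins; the consensus is the intensity-weighted mean and the
residual (max deviation) must pass a tolerance or the call errors rather
than guessing. It is exact on clean series and degrades gracefully under
m/z jitter; it is not a Bayesian mixture deconvolution and will not
separate overlapping species.

## Synthetic generators: what they emulate, and what they don't

All generators are pure functions of their arguments and a seed (a private
RNG stream leaves the caller's RNG untouched).

- `make_two_module_model` emulates the *geometry* of the swivel
  measurement: two rigid pseudo-Cα clouds of realistic spatial extent
  (~100 Å), a bridge-helix marker line through the rotation axis, a known
  applied rotation, and i.i.d. Gaussian coordinate noise. It does not
  emulate correlated model-building error, missing residues, or internal
  domain deformation — so passing recovery tests demonstrate numerical
  correctness, not robustness to real cryo-EM artefacts.
- `make_duplex` builds full heavy-atom duplexes from idealized planar base
  templates (MMFF94-optimised N-methyl nucleobases, flattened; shipped as
  data) whose pair geometry is solved once, deterministically, against
  2.9 Å donor–acceptor targets, then stacked with A-form fibre parameters
  (twist 32.7°, rise 2.81 Å, axis offset 4.4 Å). Sugar/phosphate geometry
  is approximate (placed per-residue, not refined for backbone
  continuity) — fine for selections, I/O and SASA fixtures, but these are
  not refinement-quality models. Options add a mid-helix bend and a
  minor-groove third strand donating one H bond per strand-1 purine.
- `make_gel_dataset` inverts the activity formula to paused fractions
  (defaults P_WT = 0.15, P_put⁻ = 0.60 — an efficient pause strongly
  suppressed by wild-type put), converts to cytosine-weighted intensities
  and applies multiplicative log-normal noise at a given CV. Real gels add
  background, saturation and lane-to-lane loading effects that the
  generator intentionally omits (background subtraction is upstream of the
  pipeline).
- `simulate_charge_series` produces clean or jittered positive-mode series
  for the deconvolution round trip.

## Problem sizes and tolerances in the test suite

The suite runs on synthetic fixtures sized for precision, not bulk:
swivel recovery uses 550-atom models over applied angles 0.5–5° at noise
σ ∈ {0, 0.3} Å (mean absolute error must stay below 0.1°); SASA oracles use
a 20-atom cluster against a 10⁵-point Monte Carlo sampler (≤ 2% per atom)
and two-sphere closed forms (≤ 2%); duplex inventories cover lengths 4–20;
gel round-trips use n = 3 replicates at 5% CV (MAE ≤ 0.05); mass round
trips cover 10–40 kDa (≤ 1e-6 Da noiseless). `scripts/acceptance.R`
recomputes all of these from a single seed in well under a minute.

## Known limitations

- Domain-boundary choices dominate swivel-angle differences at the few-
  tenths-of-a-degree level; the packaged config is a curated starting
  point, not ground truth.
- Interface areas depend on the radii table at the few-percent level;
  cross-tool comparisons should expect ±10%.
- The Saenger catalog covers only the classes listed above.
- The hybrid register requires the caller to identify the downstream
  junction; the package will not guess it.
- No electrostatics, no interface free energies, no water-mediated
  contacts, no cryo-EM map handling, no model refinement.
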