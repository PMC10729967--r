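---
title: "Models and methods behind catchdmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind catchdmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchdmd)
```

## The scientific problem

CATCH peptides (Co-Assembly Tags based on CHarge complementarity) are pairs
of 11-mer peptides following the pattern CQCFCFCFCQC, where the C positions
carry either six lysines (KQKFKFKFKQK, net charge +6) or six glutamates /
aspartates (EQEFEFEFEQE or DQDFDFDFDQD, net charge −6).  Mixed together,
the oppositely charged peptides co-assemble into antiparallel β-sheet
bilayers with a buried phenylalanine core; alone, like-charge repulsion
keeps them as random coils.  Replacing glutamate by aspartate — one
methylene shorter — changes fibre morphology (twist, bilayer stacking) and
slows co-assembly.

`catchdmd` provides the computational machinery to study this system at
desk scale: an ideal β-sheet bilayer constructor with prescribed geometry;
a coarse-grained event-driven (discontinuous) molecular-dynamics engine over
a four-bead peptide model; the structural analyses (twist, plane-fit sheet
separations, hydrogen bonds and salt bridges, contact maps, RMSD,
secondary-structure aggregation); and graph-based assembly kinetics with
β-barrel detection.

## The four-bead square-well model

Each residue is represented by three backbone beads (NH, Cα, CO; united-atom
masses 15.015, 13.019 and 28.010 amu) and one sidechain bead R carrying the
residue's sidechain mass (glycine has no R bead).  Covalent bonds (NH–Cα,
Cα–CO, CO–NH′, Cα–R) and geometry-maintaining pseudobonds (NH–CO within a
residue, Cα–Cα′, Cα–NH′, CO–Cα′, R–NH, R–CO) are hard walls that keep each
pair within ±2.375 % of its nominal length.  This pseudobond set fixes bond
angles and the trans peptide plane while leaving the φ/ψ torsions exactly
free: a rotation of the downstream chain about the NH–Cα or Cα–CO axis
preserves every wall identically, which is both how the model expresses
backbone flexibility and how the random-coil generator works (pivot moves
with hard-core rejection — a self-avoiding walk in torsion space).

Nominal bond lengths derive from a single reference conformation: an
extended β-strand with Cα beads on the strand axis (rise 3.5 Å per residue),
NH/CO beads zig-zagging laterally in the backbone plane (the lateral offset
is solved numerically so that NH–Cα = 1.46, Cα–CO = 1.51 and the peptide
bond CO–NH′ = 1.33 Å exactly), and sidechain beads pleated perpendicular to
the backbone plane on alternating sides.  Because every nominal length is
measured on this template, ideal builds satisfy all constraints to machine
precision.  The template backbone is planar, which makes it achiral; strand
reversal is therefore modelled by a y-reflection without a chirality
penalty.  This is a deliberate simplification — real β-strands are chiral,
and the left-handed twist the atomistic work reports emerges from that
chirality.  Here twist is *prescribed* by the builder and *measured* by the
metrics, not emergent.

### Interactions

Non-bonded interactions are hard cores plus optional square wells.  Beads in
the same or adjacent residues of one peptide interact only through their
bond walls.  Published parameter sets for this model class cover all 210
sidechain pairs; they live outside this package, so `catchdmd` ships a
documented stand-in default (`default_interaction_table()`) that preserves
the interaction structure that drives charge-complementary co-assembly:

* **F–F**: attractive, depth −1 (in units of the hydrogen-bond energy),
  range σ + 1.5 Å — the hydrophobic core;
* **cation–anion** (K–E, K–D, …): attractive, with both the reach and the
  depth of the well growing with the combined sidechain length
  L<sub>i</sub> + L<sub>j</sub> (L = Cα–R bond length): range
  σ + 0.4 + 0.5 (L<sub>i</sub> + L<sub>j</sub>), depth
  −((L<sub>i</sub> + L<sub>j</sub>)/(L<sub>K</sub> + L<sub>E</sub>))³.  The
  longer glutamate therefore gives the K–E pair a greater range than K–D
  (λ = 8.05 vs 7.55 Å) and a ~1.4× deeper well (−1.0 vs −0.74), matching
  the interaction-strength contrast measured for these two salt-bridge
  pairs by titration calorimetry and interaction-energy analyses.  This
  pair of rules is the table's central design choice: greater range *and*
  greater strength of the glutamate pair are the stated mechanisms for the
  faster co-assembly of the K/E system, and without the depth contrast the
  aspartate bead's closer backbone approach cancels the range advantage at
  desk scale;
* **like-charge pairs** (K–K, E–E, D–D, E–D, …): a repulsive square
  shoulder (+0.5, range σ + 0.4 + 0.25 (L<sub>i</sub> + L<sub>j</sub>)).
  This deviates from treating like charges as plain hard spheres, and
  deliberately: without the shoulder two like-charged peptides can zip into
  a backbone hydrogen-bond ladder held together by their hydrophobic faces,
  destroying the selectivity that defines the CATCH system — charge
  repulsion discouraging self-assembly is as much part of the mechanism as
  charge complementarity driving co-assembly;
* **all remaining pairs**: hard spheres only.

Any entry can be overridden via a YAML table
(`write_interaction_table()` / `read_interaction_table()`).

Hydrogen bonds are directional square-well associations between backbone NH
and CO beads: association range 4.2 Å, depth ε<sub>HB</sub> = 12.47 kJ/mol
(the unit of reduced energy), at most one partner per NH and per CO.
Directionality is enforced by four auxiliary minimum-distance criteria
(4.2 Å) evaluated at the association instant between the donor's Cα and
preceding CO, the acceptor's Cα and following NH, and the opposite partner —
the established mechanism for square-well hydrogen bonding; an association
attempt failing the criteria passes through without interaction.  These
settings let the ideal antiparallel sheet (5 Å strand spacing) form its full
hydrogen-bond ladder while rejecting most misoriented encounters.

### Reduced units

Lengths are in Å, masses in amu, energies in ε<sub>HB</sub>; the derived
time unit is τ = √(amu Å² / ε<sub>HB</sub>) ≈ 0.28 ps.  The reduced
temperature is T\* = k<sub>B</sub>T/ε<sub>HB</sub>; by this definition
T\* = 0.18 corresponds to ≈ 270 K.  Calibrations of this model family
against experimental temperatures place the same state point nearer 296 K;
that mapping is external to the formula, so the package exposes the
definition only and asserts neither correspondence.  Likewise the mapping
from event counts to physical microseconds used in large-scale studies is
not derivable from in-package quantities; all reported times are reduced.

## The event-driven engine

Between events every bead moves ballistically; events are exact
quadratic-root crossings: hard-core collisions, well boundaries (capture
with a radial speed-up worth exactly |ε|; escape when the radial kinetic
energy suffices, elastic bounce otherwise), bond walls, hydrogen-bond
association/dissociation, Andersen-thermostat ghost collisions
(Poisson-timed velocity redraws at `ghost_rate` per bead per τ), and
cell-list crossings.  Implementation choices that matter:

* a binary-heap event queue holding, for each bead, its earliest candidate
  event; per-bead epoch counters invalidate events after any velocity
  change, and a stale pop reschedules the members that are still valid
  (this keeps the queue small without missing events);
* cell events carry their crossing axis and direction so cell stepping is
  exact at boundaries;
* positions update lazily (per-bead timestamps), so energy conservation is
  limited only by round-off: microcanonical drift is ~10⁻¹³ relative over
  10⁵ events, against a requirement of 10⁻⁸;
* ties in the queue break on (time, kind, bead indices) and all randomness
  flows from one seeded generator, so runs are bit-reproducible for a given
  seed;
* the engine's incremental energy log is cross-checked in the tests against
  an independent O(N²) evaluation (`total_energy()`).

Momentum is conserved exactly by every two-body update; the thermostat
intentionally does not conserve it.  Instantaneous temperature uses all 3N
momentum degrees of freedom — bond walls are stepwise potentials, not
holonomic constraints, so no degrees of freedom are removed.

## The structure builders as synthetic data

The builders construct the study conditions and double as the test-data
generators: every product carries a `ground_truth` attribute with the
parameters used, and the test suite checks that the metrics recover them
(twist to 0.05°, spacing to 0.01 Å on noiseless builds).

* `build_sheet()`: in-register antiparallel sheets with alternating peptide
  charge and orientation, 5 Å strand spacing, and a uniform per-strand
  twist about the fibril axis (negative = left-handed).  For the palindromic
  CATCH pattern the antiparallel flip aligns residue *classes* laterally;
  index-level registration is not geometrically attainable for antiparallel
  strands under proper rotations.
* `build_bilayer()`: two sheets 13 Å apart, phenylalanine faces buried.
* `build_two_bilayers()`: four sheets; the charged faces of sheets 2 and 3
  meet across the inter-bilayer gap.  In stacked mode their sidechain tip
  planes sit 3 Å apart; in separated mode 13 Å (10 Å more).  Tip planes are
  the backbone plane offset by the mean extended reach of the face's charged
  sidechains; the reach table (K 6.40, E 5.40, D 3.30 Å) represents extended
  rotamer extents anchored so that the 3 Å-tip construction reproduces the
  published initial plane-fit distances: 14.8 Å for K/E and 12.7 Å for K/D.
* `random_coil_box()`: the DMD starting condition — random-coil conformers
  at random positions/orientations in a periodic cube with a minimum
  inter-peptide separation and Maxwell–Boltzmann velocities.
* `scripted_trajectory()`: frames with prescribed cluster membership,
  hydrogen-bond ladders and classes (sheet / barrel / oligomer), the ground
  truth for the kinetics pipeline, including barrel-opening events.

What the synthetic data deliberately do **not** emulate: solvent and
counter-ions (the model is implicit-solvent), backbone chirality (above),
emergent twist, and the published parameter tables themselves.  Passing
tests therefore demonstrate the correctness of the machinery — builders,
engine mechanics, detectors, classifiers — under a faithful model *class*,
not a quantitative reproduction of the published trajectories.

## Structural metrics

Twist: each strand axis is the total-least-squares line through its Cα
positions, oriented N→C; neighbouring axes are aligned (antiparallel
partners flipped) and the signed angle uses the strand-stacking direction
as the sign reference, negative = left-handed.  Sheet separation: planes are
total-least-squares fits to each sheet's backbone beads and the separation
is the distance between plane centroids.  Hydrogen bonds and salt bridges
use the geometric criteria H···A ≤ 3.0 Å and donor–H···A ≥ 135°, with
ammonium hydrogens (K) as donors and carboxylate oxygens (D/E) as acceptors
for salt bridges; the bonding angle is interpreted as N–H···O.  Contacts use
a 7 Å all-atom cutoff grouped by residue pair, excluding intra-residue pairs
by default (configurable) since self-contacts carry no interaction meaning.
RMSD is Kabsch superposition with a determinant-corrected rotation.
Secondary-structure aggregation consumes per-frame, per-residue class
assignments from an external assigner and reports mean occupancies and
class totals, with the three helix classes (3–10, α, π) merged into one
helix total; the package ships the published per-residue monomer table as a
worked example (`catch_monomer_secondary()`), whose self-consistent columns
sum exactly to their printed totals.

## Assembly kinetics

Two peptides are connected when they share ≥ 5 hydrogen bonds or ≥ 2
hydrophobic sidechain contacts (a hydrophobic contact is a
hydrophobic-class R–R pair within its square-well range).  Clusters are the
connected components.  Classification works on the β-ladder subgraph (links
with ≥ 5 hydrogen bonds): a single cycle through all members is a β-barrel,
a single path with ≥ 4 members a β-sheet, anything else of size > 1 an
oligomer.  The time series counts peptides as free / oligomeric / fibrillar
(β-sheet ∪ β-barrel) — cluster counts are reported alongside since either
convention is defensible — and transitions are logged when a cluster tracked
by > 50 % member overlap changes class between consecutive frames (e.g. a
β-barrel opening into a β-sheet).  A "fibril" here is any ladder-classified
cluster of ≥ 4 strands; the retrospective definition (the final β-sheet of a
run) is unusable online.

## Desk-scale study conditions

The published simulations use 200 peptides in a 321 Å box (20 mM) for
~5 × 10¹¹ collisions.  The package's comparative-kinetics conditions are
scaled to a single CPU: 10 + 10 peptides in an 80 Å box (~65 mM — denser, so
that diffusive encounters happen within the budget; at 20 mM and desk-scale
event budgets neither system meets often enough to assemble), T\* = 0.18,
ghost rate 0.005 per bead per τ (transport stays nearly ballistic between
kicks), 1600 τ per run sampled every 50 τ, ten seed-matched replicates per
system.  The comparison statistic is the median time to reach half of each
run's final hydrogen-bond count.  A candid caveat: at this scale the
replicate-to-replicate spread of that statistic is of the same order as the
difference between the two systems' medians, so while the glutamate mixture
reaches its half-count earlier at these conditions, the margin is thin —
across exploratory condition sets (shorter horizons, other seed sets) the
sample medians favoured either system about equally often.  The comparison
is retained as an honest check of what desk-scale simulation can and cannot
show; resolving the ordering decisively appears to need the averaging that
the published 200-peptide, half-trillion-collision conditions provide.  The
acceptance script reruns a six-replicate version of the same comparison
from its command-line seed and reports both medians and their ordering.

## Numerical choices and degenerate inputs

Well-boundary classification uses a relative tolerance of 10⁻⁹ with the
radial velocity sign as tie-breaker, so captures/escapes at a boundary are
never double-counted.  Overlapping non-bonded beads, bond-wall violations
and registry inconsistencies are rejected at run start, never silently
fixed.  Degenerate metric inputs (fewer than 3 points, collinear plane
fits, zero axes, empty selections) raise errors.  Events tie-break
deterministically; equal-time events process in bead-index order.

## Known limitations

* The interaction table is a stand-in: absolute rates, absolute hydrogen
  bond counts and cluster size distributions are not quantitative
  predictions; only relative, mechanism-level comparisons are meaningful.
* The achiral template means twist must be prescribed, not discovered.
* MM/GBSA- and LIE-style interaction energies are out of scope; the contact
  count between selections (`group_contacts()`) is the in-package proxy.
* DSSP assignment is consumed, not computed.
* No pressure coupling, no replica exchange, no continuous potentials.
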