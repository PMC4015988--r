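---
title: "Methods: building, simulating and classifying single-sheet cross-beta aggregates"
author: "crossbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building, simulating and classifying single-sheet cross-beta aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific setting

The heptapeptide GNNQQNY (residues 7-13 of the yeast prion protein Sup35)
forms amyloid fibrils on its own, and its microcrystal structure shows the
presumed first stage of fibril assembly: a planar, in-register, parallel
single beta-sheet in which every strand is extended and successive strands
stack at the canonical cross-beta spacing.  Three point mutations -- N2D
(GDNQQNY), N2S (GSNQQNY) and N6D (GNNQQDY) -- impair aggregation of the
full-length protein, and molecular-dynamics studies of pre-formed
single-sheet aggregates of these variants ask whether the mutations
destabilize the aggregate even in the peptide context.  The experimental
design varies four factors: mutant, sheet size (5-8 peptides), temperature
(300/330 K) and termini protonation (charged NH3+/COO- versus neutral
NH2/COOH), and classifies each run as *stable* or *unstable*, naming for
unstable runs a key molecular event: disorder, dissociation,
rearrangement, disintegration or collapse.

`crossbeta` implements the full analysis side of that design at desk
scale.  It does **not** run molecular dynamics.  Instead it (i) encodes
the study design and its reference outcomes as data, (ii) builds
idealized aggregates, (iii) generates synthetic trajectories in which the
events of interest are scripted kinematically, and (iv) implements the
observable and classification layer that turns a trajectory -- synthetic
or user-supplied -- into per-frame observables, event records and a
stability verdict.  The synthetic route makes every classification rule
testable against known ground truth.

## The encoded study design

`enumerate_plan()` expands the 3 x 4 x 2 x 2 factor matrix (48 systems)
plus one extra replicate for each of the two re-seeded runs (6N2D\*/300
and 7N2S\*/330), giving 50 simulations named `nXpY` with a trailing `*`
for neutral termini.  `load_reference_outcomes()` returns the packaged
verdict table: one row per system and temperature with the 50 ns verdict,
the key event, and flags for the six runs extended to 100 ns, the two
re-seeded runs, and the single system that became unstable only during
its extension (5N2S\*/330, dissociation at about 95 ns).  We deliberately
keep the 50 ns verdict single-valued: late instability is a flag, not a
verdict change, so that "stable" always means "stable at the 50 ns
horizon".

## Builder geometry

Strands are built heavy-atom-only from internal coordinates with ideal
extended-strand dihedrals (phi = -120 deg, psi = +120 deg, omega = 180
deg) and standard bond lengths and angles; the consecutive Ca-Ca distance
comes out at 0.380 nm.  Sheets stack copies of the strand along +y at a
default spacing of 0.48 nm, the canonical cross-beta inter-strand
distance (the source model prints no internal coordinates, so both the
idealized geometry and the spacing are conventions, exposed in
`aggregate_spec()`).

Two orientation choices are fixed numerically, once, and frozen:

* **Strand roll.**  The strand is oriented with its Ca2-Ca6 axis along
  +x and rolled about that axis by 55 degrees.  Across the 35-70 degree
  range both backbone hydrogen-bond ladders of a strand pair form (amide
  of residue r donating to the carbonyl of residue r-1 of the adjacent
  strand, odd residues donating up-sheet and even residues down-sheet,
  N...O about 0.27-0.28 nm); 55 degrees is the centre of that plateau.
* **Side-chain rotamers.**  One fixed rotamer per residue type, chosen
  from a geometric scan so that the Asn and Gln amides form the
  in-register side-chain ladders of a polar zipper at the default
  spacing (Asn chi1 = -60, chi2 = 150; Gln chi1 = 150, chi2 = 180,
  chi3 = 90; Asp mirrors Asn; Ser chi1 = -60; Tyr chi1 = 180, chi2 = 90).
  An all-anti rotamer would orient the amide planes so that no ladder
  forms at 0.48 nm, which would make the built sheets chemically inert;
  the zipper-aligned rotamer is therefore part of the model definition.

Two structural consequences of this template are worth knowing:

* Side-chain donation is *directional by residue parity*: the 2/4/6 face
  donates up-sheet, the 1/3/5/7 face down-sheet.  The top strand is
  therefore the one whose N2/Q4/N6 donors are unsatisfied (they would
  hydrogen-bond with solvent) and the bottom strand the one whose
  odd-face donors are unsatisfied -- exactly the N-edge/C-edge
  distinction, which `classify_edge()` operationalizes through donated
  side-chain hydrogen bonds.  A symmetric participation count could not
  tell the two edges of a translationally periodic sheet apart.
* The mutations thin the zipper exactly as expected: Ser2 cannot reach
  the neighbouring hydroxyl (no position-2 ladder), and the Asp
  carboxylate has no donor (no ladder at the mutated position at all).

Antiparallel pairs are built, and the scripted rearrangement event is
realized, by a 180-degree rotation about the *sheet-plane normal* through
the strand centre.  A rotation about the strand axis itself would leave
the Ca2-Ca6 vector -- and hence the twist-based orientation measure --
unchanged, so it cannot produce an antiparallel reading; the in-plane
flip reverses the strand direction, which is what "antiparallel" means
here.  Antiparallel *builds* need a spacing of about 0.55 nm or more;
at 0.48 nm the fixed rotamers of facing strands interpenetrate and the
builder raises its steric-clash error (any inter-peptide heavy-atom
distance below 0.15 nm).

## Synthetic trajectories

`generate_trajectory()` renders a `scenario_script()`: frame *t* is the
starting frame with each scheduled event applied at linear progress
`(t - start)/(end - start)`, clamped to [0, 1] (equal start and end give
a step), plus thermal positional noise.  Scripted kinematics:

| event | realization | main defaults |
|---|---|---|
| `progressive_twist` | cumulative per-pair rotation about the stacking axis | 15 deg/pair |
| `end_fray` | hinge rotation of a terminal residue run about the adjacent Ca | residue 1, 45 deg |
| `disorder` | per-residue phi/psi jitter, centre of mass pinned | sigma 25 deg |
| `dissociation` | rigid translation away from the aggregate | 2.0 nm |
| `rearrangement` | 180-degree flip of one strand about the sheet normal | 180 deg |
| `disintegration` | rigid block translations along the block-to-rest axis | 2.0 nm |
| `collapse` | radial contraction of strand centres plus per-strand orientation randomization | factor 0.7, up to 90 deg |

**Noise model.**  `noise_sigma` is the root-mean-square *total*
displacement per atom in nm (per-axis standard deviation
`noise_sigma/sqrt(3)`), drawn independently per atom and frame about the
scripted geometry -- noise is not a random walk, so the scripted pose is
the mean and parameter recovery is well-posed.  Each peptide's best-fit
rigid component (net translation and infinitesimal rotation) is removed
from the noise field, so centres of mass do not jitter.  The rms
convention matters: with a per-axis reading of the same number, the
unsigned-angle folding bias at zero true twist
(E = sigma_angle x sqrt(pi/2), about 2.2 degrees at 0.02 nm) would
exceed the 2-degree recovery tolerance the package holds itself to; under
the rms convention the bias is about 1.3 degrees and twist recovery is
unbiased within tolerance at all tested angles.

Scripts are validated: event windows must lie inside the frame range, a
dissociation names exactly one peptide, a disintegration a partition into
at least two blocks, and two displacement-type events that overlap in
time on a shared peptide are rejected as contradictory.  Output is fully
determined by `(frame0, script)` including the seed, and generation
restores the caller's RNG state.

`preset_scenarios()` ships seven named scripts (the six canonical ones
plus `edge_disorder`), each carrying the verdict and key event it is
constructed to produce.  The disorder preset uses a 50-degree jitter
rather than the 25-degree event default: the preset's purpose is to
exhibit a complete conformational melt of one strand, and 25 degrees
leaves enough residual ladder to fall short of the disorder trigger.

## Observables

* **Rg** is mass-weighted (the usual analysis-tool default; the
  source analyses do not state the choice).  The stability drift
  `delta_rg()` is the mean over the final 5% of frames minus the mean
  over the first 5% (at least one frame each); a single-frame endpoint
  mode is available for strict parity with a final-minus-initial rule.
* **Pair twist** is the unsigned angle in [0, 180] degrees between the
  Ca2-to-Ca6 vectors of two peptides.  Because the builder keeps that
  vector exactly perpendicular to the stacking axis, an imposed per-pair
  twist is recovered exactly (to floating-point) on noise-free builds.
* **Hydrogen bonds** use a geometric heavy-atom criterion:
  donor-acceptor distance at most 0.35 nm and antecedent-donor-acceptor
  angle at least 90 degrees (the source counts came from an MD package's
  defaults and state no criterion; ours is exposed in `cb_config()`).
  Donor/acceptor roles follow residue chemistry and the termini state:
  charged N-terminus donates only, charged C-terminal O/OXT accept only,
  the neutral carboxylic acid exposes one donor and one acceptor.
  Same-residue pairs and the backbone amide with its covalently adjacent
  carbonyl are excluded.
* **Tyrosine stacking** uses the symmetrized centroid-to-plane
  projection (mean of the two centroid-difference projections onto the
  best-fit ring normals); a plain centroid-centroid mode is available
  since the printed criterion ("distance between the ring planes
  < 0.5 nm") does not fix the construction.  The stacking flag is strict:
  exactly 0.5 nm is not stacked.
* **Sheet assignment** is a ladder test, not full 8-state DSSP: a
  residue is marked when it participates directly in an inter-peptide
  backbone-backbone bond or sits on a parallel beta-bridge (`N(q,i)` to
  `O(p,i-1)` together with `N(p,i+1)` to `O(q,i)`), and marked residues
  in runs of two or more are labelled E.  The event layer uses the
  *strict* (bridge-only) form: in densely packed amorphous geometries,
  incidental backbone contacts satisfy the single-bond criterion but not
  the coordinated two-bond pattern, and the strict form is what cleanly
  separates a collapsed blob from a sheet.

## Event layer

Peptides are clustered per frame: connected when sharing at least two
inter-peptide backbone-backbone hydrogen bonds or within 0.45 nm minimum
heavy-atom distance; the partition is the connected components.  Every
trigger must hold for a persistence window of 5 consecutive frames --
the source relied on visual trajectory inspection, which this layer
replaces with explicit, documented rules:

* **dissociation** -- a singleton leaves the main cluster (the cluster
  tracked from the initial largest one by maximal member overlap, ties
  to the lexicographically smallest set);
* **disintegration** -- the main cluster splits into two or more blocks
  of at least two peptides;
* **rearrangement** -- an initially adjacent pair of *still-extended*
  strands changes orientation class (parallel < 50 deg, antiparallel
  > 130 deg, crossed between -- thresholds symmetric about 90 since no
  boundary is printed) or shifts register by one or more residues, while
  staying in one cluster.  Restricting to initially adjacent pairs is
  essential: in a cumulatively twisted sheet, distant pairs legitimately
  exceed 50 degrees without any reorganization;
* **disorder** -- a peptide crumples: sheet content below two residues
  *and* loss of extended-strand geometry (Ca1-Ca7 end-to-end below
  1.9 nm against 1.99 nm for the ideal strand), while the rest of the
  cluster stays ordered;
* **collapse** -- aggregate Rg at least 0.1 nm below its initial value
  together with mean strict sheet content below half its initial value.

Three attribution rules keep the taxonomy mutually exclusive where the
signals overlap.  A crumpling strand transits a bent-but-still-extended
phase that can read as an orientation change, so a disorder record vetoes
rearrangement records involving the same peptide.  Conversely the
extendedness gate stops a rigid flip (which keeps its full end-to-end
length) from ever reading as disorder.  And a detected collapse subsumes
rearrangement and disorder records whose onsets fall in the global
contraction leading to it -- during an amorphous collapse every pair
reorients, and reporting those as rearrangements would mislabel the
aggregate-level event.

**Verdict.**  An aggregate is stable when it retains its initial
organization to the end: |dRg| strictly below 0.1 nm, no sustained event
of *any* of the five types, and no peptide detached in the final frame.
The reference table lists systems that are "Unstable -- Disorder" and
"Unstable -- Rearrangement", i.e. its stability notion treats those
events as organization changes too, so the gate here includes them
rather than only the three terminal events.  The key event of an
unstable run is the earliest record (ties broken from aggregate-level to
peptide-level).

**Census.**  `oligomer_census()` tracks every cluster of two or more
peptides with constant membership, tolerating interruptions shorter than
the persistence window; lifetime is `(death - birth) x frame_dt` with
death at `n_frames` for clusters alive at the end.  Orientation classes
of connected member pairs and mean strict sheet content are summarised at
the record's mid-life frame; `ordered` means at least half the ladder
positions are kept.

## Numerical choices and degenerate inputs

All coordinates are nm, angles degrees, times ns; PDB I/O converts to
Angstrom and round-trips coordinates to the format's 0.001 Angstrom
precision.  The identity rigid transform returns its input bitwise.
Unsigned angles clamp the cosine into [-1, 1] before `acos`.  Frames
without a complete residue-1-to-7 backbone are treated as "extendedness
not assessable" (never disordered by that gate alone).  A two-peptide
system has no interior peptides; `residue_profiles(..., exclude_edges =
TRUE)` then warns and flags the result rather than silently averaging
edges.  Cluster tie-breaks and event orderings are deterministic, so
identical trajectories always give identical reports.

## Problem sizes and what the tests show

The test suite and the acceptance script work at desk scale: sheets of
5-8 peptides (about 350-570 heavy atoms), trajectories of 100 frames at
0.5 ns/frame (a 50 ns analogue of the study's time axis at far lower
frame density), and scenario-recovery sweeps of 6 scenarios x 10 seeds
at 0.01 nm noise.  These sizes were chosen as the smallest that exercise
every rule meaningfully.

Passing the recovery tests shows that the classification layer inverts
the generator's event taxonomy reliably under the stated noise model.  It
does **not** show that the rules would classify real MD trajectories with
the same accuracy: real data have correlated thermal motion, partial and
transient events, solvent-mediated interactions and force-field-specific
hydrogen-bond geometry, none of which the generator emulates.  The
package's claim on real data is therefore only that its observables
implement the printed criteria (0.5 nm stacking, 0.1 nm dRg gate, the
twist definition) and that its event rules are explicit and
reproducible where the original classification was visual.

## Known limitations

* Single-sheet systems only; double-layer/steric-zipper builds are out
  of scope.
* Heavy atoms only; hydrogen positions are never modelled and the
  hydrogen-bond test is purely geometric on donors/acceptors.
* One fixed rotamer per residue type; no rotamer search, so built
  side-chain contacts are idealized.
* Temperature is metadata, not physics: a 330 K system differs from a
  300 K one only by which reference outcome it is compared against.
* The sheet ladder test knows parallel bridges only; after large
  reorientations (e.g. an antiparallel flip) reformed sheets are seen by
  the contact/participation machinery but not credited as bridges.
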