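---
title: "Geometric descriptors of binding-pocket dynamics in a pentameric receptor ECD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric descriptors of binding-pocket dynamics in a pentameric receptor ECD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentapocket)
```

## The system and the problem

Pentameric ligand-gated ion channels (pLGICs) carry five orthosteric
agonist-binding pockets, one at each interface between a *principal* (+) and
a *complementary* (−) subunit of the extracellular domain (ECD). In the
homomeric glycine receptor every subunit therefore participates in two
pockets: loops A–C and Loop 2 on its principal face, loops D–F on its
complementary face. Agonist binding caps the pocket with Loop C, squeezes
water out, contracts the interface, and — because Loop B of one pocket is
covalently linked to Loop F of the adjacent pocket through the shared
subunit — can push or pull on the neighbouring binding site.

`pentapocket` computes the per-frame geometric descriptors that make these
statements quantitative for an MD trajectory of an ECD pentamer:

* hydrogen bonds, water-bridged contacts and cation–π interactions between
  the ligand and the binding residues, aggregated into occurrence tables;
* a convex-hull "atomic cage" over the Cα atoms of the 11 binding residues,
  giving an interior water count and a pocket-volume estimate per frame;
* a Loop C orientation angle built from three anchor-pair centroids;
* assembly metrics: backbone RMSD, per-loop RMSF, intersubunit Cα contact
  maps, planar intra-/interpocket centroid distances, adjacent-pocket
  Loop C angle correlations, and the push–pull distance analysis;
* the two collective variables used to eject a ligand in enhanced-sampling
  runs: binding-site COM distance and a solvation coordination number.

## Geometric definitions and defaults

All coordinates are ångström internally; XTC's native nanometres are not an
issue because XTC is not read (no reader exists in the supported stack —
use DCD or multi-model PDB).

**Hydrogen bond.** Donor–acceptor heavy-atom distance ≤ 3.0 Å and
donor–H–acceptor angle ≥ 135° (180° = linear). Donors are N/O atoms with a
covalently bound hydrogen (≤ 1.2 Å); acceptors are all N/O atoms. A salt
bridge is reported as its constituent hydrogen bonds — occurrence tables
count it among hydrogen bonds rather than as a separate category.

**Water bridge.** One record per (residue, water molecule) and frame in
which a single water simultaneously forms at least one hydrogen bond with
the ligand and at least one with the residue. A direct ligand–residue bond
is never double-counted as a bridge, and multiple bond geometries through
the same water still count once — the conservative reading of per-residue
occurrence.

**Cation–π.** Cation position is the ligand ammonium nitrogen
(config-exposed). Ring centre is the unweighted centroid of the six ring
atoms of PHE/TYR; the normal is the best-fit plane normal (smallest
singular vector). Interaction requires centre distance ≤ 6 Å and an angle
between the normal and the centre→cation direction < 45° or > 135°.

**Atomic cage.** The convex hull of the 11 binding-residue Cα atoms
(7 principal: PHE115, GLU173, SER174, PHE175, TYR218, THR220, PHE223;
4 complementary: PHE79, ARG81, LEU133, SER145), rebuilt at every frame.
The hull is computed in-package by supporting-plane enumeration with
coplanar-face merging — appropriate for 11 points, exact for the coplanar
faces of degenerate fixtures, and validated in the test suite against qhull
and Monte-Carlo rejection volumes plus a simplex-decomposition membership
oracle. Water oxygens on a face plane (tolerance 1e-9 Å) count as inside so
that floating-point ties are deterministic.

**Loop C angle.** Three centroids: apex C (ASN219/THR220 Cα), hinge O
(THR215/THR224), complementary reference G (ASN58/ARG81). The reported
angle is at the hinge vertex between rays O→C and O→G. The hinge is used
as the vertex because the loop pivots there; the `vertex` argument allows
apex- or reference-vertex variants for sensitivity analysis. Small angles
(~22–26°) indicate a capped, ligand-bound pocket; large angles (~31–35°)
an open one.

**Channel axis and planar distances.** The pseudo-C5 axis is the
eigenvector of the protein Cα gyration tensor whose eigenvalue is farthest
from the other two (the unique small-spread axis of a ring-like assembly),
sign-oriented from the restrained C-terminal tail (residues 236–240) toward
the overall centroid. This is parameter-free and stable for a ring; a fixed
axis can be supplied instead. Intrapocket distance: planar (axis-orthogonal)
distance between a pocket's principal- and complementary-side binding-residue
centroids ("centre of mass of the Cα" is implemented as the unweighted
centroid — all Cα are carbons of equal mass). Interpocket distance "x-y":
the planar distance between the complementary-side centroid of pocket x and
the principal-side centroid of pocket y, the two centroids residing on one
subunit. Distances are measured per frame and averaged; a `between_means`
flag measures once between time-averaged centroids instead.

**Contact maps.** Occurrence fraction of Cα–Cα distances strictly below
11 Å between principal- and complementary-subunit residues, averaged over
frames.

**RMSD / RMSF.** Backbone RMSD per subunit against the first frame after
optimal superposition. RMSF is two-pass: superpose every frame's subunit
backbone on the first frame, form the average structure, re-superpose on
that average, then report per-residue Cα fluctuations. Superposition uses
the subunit backbone; the fitting selection is not dictated by the angle or
cage definitions. Both use the standard Kabsch fit from `bio3d`.

**Collective variables.** Binding-site COM distance is the distance between
mass-weighted centroids of the ligand and of the binding residues. The
solvation coordination sums, over ligand carbons i (both carbons of the
zwitterion) and water oxygens j within a hard 10 Å cutoff, the rational
switching term (1 − (d_ij/d0)^6)/(1 − (d_ij/d0)^10) with d0 = 2.5 Å. The
removable singularity at d = d0 is evaluated as its limit 6/10. The cutoff
acts as hard pair inclusion without shifting; the resulting discontinuity
at 10 Å is at most the term value there (≈ 0.004) and is accepted as part
of the printed definition. The well-tempered metadynamics engine that would
bias these CVs (bias factor 15, Gaussian widths 0.15 Å and 0.03, height
1.2 kJ/mol) is deliberately out of scope; only the CVs are computed.

## The synthetic pentamer generator

Real pLGIC trajectories are hundreds of gigabytes; the package is instead
exercised end-to-end on a C5-symmetric pseudo-pentamer whose every
descriptor has a known, scripted ground truth (`generator_params()`,
`generate_trajectory()`, `ground_truth_ledger()`).

Each subunit is a minimal residue scaffold, not a physical protein: the
descriptors are purely geometric, so the generator scripts geometry
directly. Five chains are placed by 72° rotations about z. Per pocket, the
7 + 4 binding-residue Cα form two centroid-zero clusters whose separation
sets the intrapocket distance; the Loop C apex pair is placed on a circle
about the hinge so that the measured angle equals the scheduled angle
exactly; the reference-pair partner mirrors ARG81 about the scripted
reference centroid for the same reason. Interior waters sit deep inside the
cage waist with >1 Å margin, so thermal noise cannot change the count.

Scripted interactions are Bernoulli events: hydrogen-bond "hydroxyl"
satellites, bridge-water units, hexagonal ring plates and conserved-pair
donor/acceptor units are placed in bond-satisfying geometry when the event
fires and parked far outside every pocket otherwise. Satellite units ride
rigidly with the thermal-noise displacement of their ligand anchor atom,
while every other atom receives independent isotropic Gaussian noise
(σ = 0.2 Å by default). This is a deliberate design choice: it keeps the
realized event rates exactly equal to the programmed Bernoulli rates under
noise, so statistical recovery tests compare measured occurrences against a
known binomial ground truth rather than against a noise-convolved one.
Random draws are seed-scoped per stream (events, push–pull latents, noise),
so changing the water schedule does not shift the interaction draws.

Default conditions mirror the bound/empty contrasts of a partially liganded
glycine receptor ECD: bound pockets contracted by 0.8 Å, Loop C at
24° ± 2° with the hydration supplied by the scripted water bridges
(≈1.4 interior waters at the default 0.70 bridge rates); empty pockets at
13.4 Å base width, Loop C 33° ± 4°, 7 scheduled waters. The ring radius
(22 Å) and base width (13.4 Å) were chosen once so that the *realized*
planar distances sit at the receptor's scale — ≈11.6 Å bound / ≈12.4 Å
empty intrapocket and ≈16–16.7 Å interpocket. Loop C swings are sinusoids
(period 100 frames) with per-pocket phase offsets of 72°, so adjacent-pocket
angle correlations are weak, as in the real system; setting
`loopc_phase = rep(0, 5)` restores exact C5 symmetry for machine-precision
equality checks. Push–pull coupling c links the scripted Loop B′ and
Loop F′ displacements through shared latent variables, so their distance
correlation equals c in the noise-free limit.

What the generator does **not** emulate: force-field energetics, realistic
water structure, side-chain chemistry, conformational transitions, or the
absolute magnitude of intersubunit hydrogen-bond totals (five conserved
pairs per interface are scripted, an order of magnitude sparser than a real
interface). Passing tests therefore certify the *descriptors* — their
formulas, invariances and statistical estimators — not any biophysical
claim about real trajectories.

## Numerical choices

* Hull construction tolerance is relative (1e-7 of the point-cloud extent);
  point-membership tolerance is 1e-9 Å with boundary points inside.
* Angles are clamped into [−1, 1] before `acos` to avoid NaN at collinear
  geometries; coincident anchor centroids raise an error rather than
  returning an arbitrary angle.
* Pearson correlations on zero-variance series raise an error
  (`loopc_correlation`) or return `NA` with a single warning
  (`pushpull_analysis`), because a rigid structure genuinely has no defined
  fluctuation correlation.
* No periodic-boundary imaging is applied: pocket analyses are local and
  inputs are assumed whole. Wrapped trajectories should be imaged upstream.
* Trajectories are read eagerly into an atoms × 3 × frames array; at the
  problem sizes this package targets (hundreds of frames, 10³–10⁵ atoms)
  this is well within memory and keeps every descriptor vectorizable.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data:
500-frame trajectories for statistical-recovery checks (occurrence rates
against 99% binomial intervals, a scripted 1 Å contraction against 3
standard errors, push–pull monotonicity over c ∈ {0, 0.5, 1}), 100 random
frames per detector for oracle-exactness checks, and 10⁶ Monte-Carlo
samples for hull-volume verification. These sizes give the statistical
tests comfortable power while keeping a full run at desk scale.

## Known limitations

* XTC reading is not supported; convert to DCD or multi-model PDB.
* Donor/acceptor chemistry is the standard N/O set; exotic donors
  (S–H, C–H) are not considered.
* The contact-map, RMSF and occurrence aggregations assume a static atom
  table across frames (no grand-canonical water).
* Only pentamers are validated; the ring logic generalizes but n ≠ 5 is
  untested and unsupported.
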