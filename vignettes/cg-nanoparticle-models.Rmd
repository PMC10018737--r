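---
title: "Building coarse-grained monolayer-protected nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building coarse-grained monolayer-protected nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgnano)
```

Functionalized metal nanoparticles are two-component assemblies: a rigid
metallic core and a self-assembled monolayer of grafted ligands that
dictates the particle's charge, hydrophobicity, and interactions.
Simulating particles larger than a few nanometers is only practical at
coarse-grained (CG) resolution, where beads stand for groups of atoms
(Martini-style 4-to-1 mapping is the default mental model here). `cgnano`
constructs such models — positions and a complete Gromacs-dialect
topology — so that the output can be energy-minimized and simulated
directly. This vignette explains the model, every tunable that matters,
the numerical choices behind the implementation, and what the test suite
does and does not demonstrate.

## Cores

### Lattice and sculpting

Bulk metals pack in a small set of crystal lattices, so a core is built
by replicating a conventional unit cell (primitive cubic, bcc, fcc, or
hcp) into a block and carving the target shape out of it. Two
conventions fix everything:

* **Touching spheres.** Nearest neighbors sit exactly two bead radii
  apart. This pins the lattice constants to $a = 2r$ (primitive),
  $a = 4r/\sqrt3$ (bcc), $a = 2\sqrt2\,r$ (fcc), and $a = 2r$ with the
  ideal axial ratio $c = 2r\sqrt{8/3}$ (hcp; the ideal ratio is our
  choice — real metals deviate by a few percent, which does not matter
  for a generic CG core). Bulk coordination is then 6, 8, 12 and 12
  respectively, which the elastic network reproduces exactly.
* **Center inclusion.** A bead survives sculpting when its *center*
  passes the analytic inside-test of the shape, boundary inclusive.
  Testing whole spheres instead would shrink every shape by one radius;
  center inclusion is the simpler convention and keeps a degenerate
  ellipsoid bead-for-bead identical to the sphere of the same radius.

The block is tiled symmetrically about the origin with a one-cell margin
beyond the shape's bounding box, so the origin is always a lattice point
and boundary beads are never missed. Supported shapes: sphere,
octahedron, cylinder, rod, square pyramid, ellipsoid, rectangular prism,
plus hollow shells. A *rod* is read as a cylinder with hemispherical
caps whose stated length is tip-to-tip (so `length >= 2 * radius`); the
distinction between "cylinder" and "rod" is otherwise arbitrary, and the
capped reading gives the rod the rounded profile synthesized rods
actually show.

Sculpting is deterministic, idempotent, and purely geometric; an 18 nm
fcc sphere of 0.17 nm beads (about 880,000 beads) builds in seconds.

### Shells

A hollow shell has no lattice. Beads are laid on a deterministic
golden-angle (Fibonacci) spiral, the standard quasi-uniform spherical
layout. The count comes from an area budget — each bead claims the
footprint of a disc of one bead radius — using the spiral's *measured*
packing efficiency of 0.715 rather than the hexagonal ideal of 0.9069:
the spiral is quasi-regular, and with the ideal value the realized mean
nearest-neighbor spacing comes out about 11% under two radii. With
0.715 the mean spacing lands on $2r$; individual spacings still scatter
by roughly ±15%, which is inherent to any spiral layout.

### Surface detection and normals

A bead is superficial when it has fewer nearest neighbors (within
$2r \pm 10^{-3} r$) than the bulk coordination of its lattice. Neighbor
search uses exact offset matching on the lattice (the candidate offsets
are generated numerically from a reference block, which also handles the
two hcp sublattices), so it is $O(N)$ and free of cutoff artifacts.
The outward normal stored per surface bead is the unit vector from the
core's center of mass to the bead. This is exact for spheres and shells
and an approximation on flat facets of the other convex shapes — a
face-center bead of a prism gets a slightly tilted normal. We accept
this because the supported shapes are convex (the radial direction never
points inward) and grafting along slightly tilted normals is relieved by
the clash-avoidance rotation step below.

## Monolayers

### How many ligands, and where

The ligand count is the core's analytic surface area divided by the
grafting density (nm² per ligand, e.g. 0.3 for alkylthiols on gold),
rounded, never below one. Anchors are then chosen to be as evenly
spread as possible: $N$ virtual sites start uniformly at random on the
unit sphere and a Metropolis–Hastings walk maximizes the summed pairwise
Euclidean (chord) distance $D_u = \sum_{i<j}\|x_i - x_j\|$ subject to
$\|x_i\| = 1$. Numerical choices, all of which are open in principle:

* chord rather than arc distance in $D_u$ (the optima coincide for the
  small-$N$ configurations with known solutions — antipodal pair,
  tetrahedron — and chords are cheaper);
* one-site Gaussian tangent proposals with $\sigma = 0.1$ rad,
  renormalized after every proposal so the constraint holds exactly at
  all times;
* effective temperature annealed linearly to zero over the budget
  (default $2000N$ proposals), starting from an energy scale matched to
  a typical proposal ($0.05\sqrt N$);
* the best-seen configuration is returned, so the objective never ends
  below its initial value, for any seed or budget.

With the default budget the optimizer reaches the analytic optima for
$N = 2$ (diameter, $D_u = 2$) and $N = 4$ (regular tetrahedron,
$D_u = 6\sqrt{8/3}$) to well within 1%.

Each site then claims the surface bead at the smallest angular distance
(arccos of the dot product of unit directions). Collisions are resolved
deterministically: the closer claim keeps the bead, the displaced site
takes the nearest bead still free. Anchors are therefore always unique,
and when there are as many sites as surface beads the mapping is a
bijection.

### Morphologies

Two-component monolayers are labeled per anchor: `homogeneous` (all
label 1); `random` (exactly `round(ratio * N)` label-1 anchors by a
seeded shuffle — reproducible under a fixed seed); `janus_{x,y,z}`
(split by coordinate along the axis with the dividing plane at the
ratio-quantile of the anchor coordinates, so the ratio controls
abundance exactly; label 1 occupies the negative side); and
`stripe_{x,y,z}` (`n_stripes` equal-width bands over the anchor extent,
alternating labels starting with 1 at the negative end; the ratio is
not used — band geometry fixes the abundances).

### Ligand construction and grafting

Ligands are built bead by bead from the attachment bead outward at their
bonded equilibrium geometry: each bead at the equilibrium bond length
from its parent, the equilibrium bending angle at the parent, and a
trans (180°) torsion, i.e. the maximally extended conformation along
the molecular axis (PC1). Without a parameter file the chain is
collinear at 0.35 nm spacing — a typical CG bond length — and that
fallback is noted in the build report, as is any individual missing
bond or angle entry. Branched ligands are laid depth-first along the
deepest subtree first, extra branches leaving the trans plane in 120°
steps; only linear ligands are exercised by the validation suite.

Grafting is rigid. Each copy is rotated so PC1 is parallel to the
anchor normal, translated so the attachment bead sits one anchor-bond
length outward from the anchor (the anchor-attachment bond length comes
from the parameter file entry for core-type/first-bead-type, else the
0.35 nm default — the binding group, e.g. the thiol sulfur, is
considered part of the anchor bead under the mapping), then spun about
its PC1 through a deterministic grid of 20 rotations 18° apart, keeping
the candidate that maximizes the minimum distance to everything already
placed. A grid rather than random rotations makes rebuilds
bit-identical. Because all operations are rigid, every grafted copy is
congruent to its built template to numerical precision, and a
freshly built particle with collinear ligands has a mean tilt angle of
exactly zero — a property the test suite uses to link the builder and
the analysis end to end.

## Topology

* **Masses.** The core must weigh what the real particle weighs: total
  mass = bulk density × analytic shape volume, converted at
  1 g cm⁻³ = 602.214 amu nm⁻³, split equally over the beads. (Gold:
  19.3 g cm⁻³. For a hollow shell the enclosed sphere volume is used,
  because a shell stands in for the solid particle whose interior beads
  were omitted for performance.) Core beads are neutral; their
  nonbonded behavior comes entirely from the user-chosen bead type
  (default `C1`, a purely hydrophobic bead).
* **Elastic network.** One harmonic bond (function type 1) per unique
  nearest-neighbor pair at the current distance ($= 2r$ on a lattice),
  with a user constant, default 32,500 kJ mol⁻¹ nm⁻². Shells get six
  nearest-neighbor bonds per bead plus a bond to the bead nearest the
  exact antipode (quasi-uniform layouts have no exact antipodal site),
  bracing the shell across its diameter.
* **Bonded terms.** Parameters are read from a Gromacs-dialect .itp
  (`bondtypes`/`angletypes`/`dihedraltypes`, function column optional),
  with lookups symmetric under tuple reversal and *all* entries for a
  repeated dihedral quadruplet retained — stacked periodic torsions are
  a normal CG idiom. Assignment walks each ligand copy center-out from
  the anchor, enumerating pairs, triplets, and quadruplets; anything
  without an entry is skipped and itemized, and the accounting
  `enumerated = assigned + skipped` is enforced exactly. An empty
  parameter set is legal and yields an elastic-network-only topology
  with a complete skip report.
* **Files.** `.gro` (nm, fixed columns, cubic box with a 2 nm margin)
  and `.pdb` (Å, via bio3d; residue names truncated to the 3-character
  PDB field) share one canonical ordering: core beads first, then
  ligands in anchor order — identical to the .itp, so indices never
  need translation. The `.top` references the nonbonded interaction
  matrix through a single `#include` line; swapping force fields is a
  one-line edit, verified byte-for-byte in the tests. The bundled
  matrix is a clearly labelled synthetic stub (placeholder LJ terms):
  real force-field matrices are distributed with their force fields and
  are the user's to supply.

## Analysis

* **Cumulative monolayer RDF.** $G_{\text{mono}}(r)$ — the fraction of
  monolayer beads within $r$ of the particle center of mass — is the
  empirical CDF of the bead distances (the Dirac-comb definition
  integrates to exactly this step function). The center of mass is
  computed over core beads only by default (the core dominates the
  mass; a flag includes ligands).
* **Thickness.** The 90% band, $r_{\max} - r_{\min}$ with
  $G(r_{\min}) = 0.05$ and $G(r_{\max}) = 0.95$, quantiles by linear
  interpolation between order statistics (the interpolation scheme is a
  free choice; it vanishes as $N$ grows — a uniform sample on
  $[0, 10]$ nm converges to 9.0 nm).
* **Tilt.** Per bead, the angle between the anchor-to-bead vector and
  the outward normal at the anchor; averaged beads-within-ligand, then
  ligands, then frames, in that order (the orderings differ only
  when ligand lengths differ). On trajectory input the normals are
  recomputed per frame from the instantaneous core center of mass.
  Beads coincident with their anchor carry no direction and are
  skipped and counted.
* **Radius of gyration.** Mass-weighted RMS distance from the center of
  mass, the standard proxy that scales with the hydrodynamic radius of
  globular particles. A builder-produced solid fcc sphere reproduces
  the uniform-ball value $R\sqrt{3/5}$ within 2% once $R \gtrsim 10$
  bead radii.
* **Bootstrap errors.** Resample-with-replacement at a fixed fraction
  of the sample (defaults: 1,000 iterations, 1%), reporting the SD of
  resampled means; small resamples are the usual blunt instrument
  against autocorrelation in simulation series. Seeded and
  reproducible.

## What the synthetic data does and does not show

The package ships a fixture generator rather than data: parameterized
linear "alkyl-like" ligands (1, 2, 3, 5 beads — the CG images of 4-,
8-, 13- and 20-carbon thiols under 4-to-1 mapping) with matching .itp
text, and a frame-series jitterer that adds seeded isotropic Gaussian
noise to ligand beads over a fixed core — the simplest stand-in for
thermal monolayer motion above an elastically networked core.

These fixtures validate geometry, bookkeeping and statistics. They do
not sample a Boltzmann ensemble: jittered frames have no excluded
volume, no bonded restoring forces, and no solvent. Passing tests
therefore demonstrate that the *builder* is exact and the *estimators*
are correct on known distributions — not that any simulated observable
(thickness, tilt, $R_g$ versus experiment) is reproduced; those require
running MD on the exported files with a real force field.

## Problem sizes in the validation suite

The suite builds cores of 1–2.5 nm (hundreds of beads), monolayers of
4–100 ligands, and one 18 nm / ~880,000-bead capacity check; optimizer
budgets in tests are a few hundred proposals per site. These sizes were
chosen so every property that is scale-free (coordination, congruence,
conservation, CDF validity) is exercised on systems small enough to
verify against brute-force oracles, with the single large build
confirming capacity.

## Known limitations

* Normals on flat facets are radial approximations (see above).
* The Metropolis schedule is heuristic; for very large $N$ the default
  budget leaves the layout short of the true optimum (it is still
  uniform enough for grafting, and the budget is a parameter).
* Inside-tests are on bead centers, so sculpted dimensions are accurate
  to ± one bead radius at the boundary.
* No Wulff/faceted equilibrium shapes, no alloyed cores, no
  surface reconstruction; morphologies are limited to the eight listed.
* The ellipsoid area uses the Thomsen approximation (≤1.1% error),
  which propagates into its ligand counts at the same order.
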