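---
title: "Methods: bead-level analysis of FG-nucleoporin assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-level analysis of FG-nucleoporin assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgassembly)
```

## The system and the model

FG-nucleoporins are intrinsically disordered proteins rich in
phenylalanine-glycine repeat motifs (FG, FxFG) that fill the central
channel of the nuclear pore complex and form the permeability barrier for
nucleocytoplasmic transport.  `fgassembly` models such proteins at one
bead per residue (a C-alpha-level backbone bead; optional extra beads per
residue are carried for side-chain-aware analyses) and provides the three
stages of a typical assembly study:

1. **Construction** of initial chain states: fully extended chains and
   worm-like-chain self-avoiding-walk (SAW) conformations, arranged as a
   tethered ring, a tethered 2D array, or a free periodic bath.
2. **Analysis**: residue contact graphs and their connected components
   (bundles), thickness distributions, cross-link events, amino-acid
   bundle propensities; lattice-based pore sizing by maximum-bottleneck
   path search; brush height, radius of gyration, and Shrake-Rupley
   solvent accessible surface area (SASA).
3. **Validation fixtures**: synthetic assemblies with planted ground
   truth -- parallel-chain bundles, cross-linked brushes, and channel
   phantoms of known bottleneck radius.

All lengths are in Angstrom internally; residue numbering is 1-based
everywhere.  The z axis is the brush axis for arrays and baths and the
ring axis for ring geometries.

## Chain generation

The SAW generator (`grow_saw_chain()`) adds one bead at a time under two
local geometric restraints: a fixed bond length of 3.7 A between
neighbouring backbone beads and a fixed bend angle for three adjacent
beads, with the dihedral drawn uniformly on the allowed circle.  Any two
beads are considered in close contact when closer than 8 A; candidate
beads violating this rule against the growing chain or against any other
chain are rejected.  Key parameter choices:

* **Bend angle, 127 degrees (default).**  The fixed three-bead angle
  follows the MARTINI coil backbone convention for polypeptides in coil
  conformations.  It is a configurable parameter of `saw_params()`.
* **Clash exemption window, sequence separation <= 2.**  Bonded
  neighbours sit at 3.7 A and second neighbours are fixed near 6.6 A by
  the bend angle; both are inside the 8 A cutoff, so applying the
  close-contact rule to them would reject every conformation.  The
  8 A rule therefore binds for separations of three and more, which also
  restricts the admissible dihedral range and stiffens the chain -- this
  is the excluded-volume behaviour the rejection rule is meant to
  produce.
* **Failure policy.**  Each bead placement attempts 50 dihedral redraws;
  exhaustion backtracks 5 residues; repeated exhaustion restarts the
  chain (up to 100 restarts) before a classed growth-failure condition is
  raised reporting the deepest residue reached.  All three limits are
  `saw_params()` fields.

Extended chains (`build_extended_chain()`) place residue i at
`anchor + (i-1) * b * direction`; the radius of gyration of such a chain
obeys the closed form `Rg = b * sqrt((N^2 - 1) / 12)`, which the test
suite uses as an independent check (about 656 A for a 614-residue
construct -- the 609-residue FG domain plus five C-terminal cysteines
representing the gold-binding linker).

## Tether geometries

* **Ring** (`place_ring_assembly()`): `n_chains / n_rows` anchors per
  concentric row, C-terminal residue of each chain fixed at its anchor.
  By default the inner-row radius is computed from the requested 60 A
  anchor spacing, `r = n_per_row * spacing / (2 * pi)` (about 382 A for
  40 anchors per row), so that adjacent inner-row anchors and radially
  adjacent rows are both 60 A apart and the minimum anchor-anchor
  distance equals the requested spacing.  With equal per-row counts and a
  fixed 60 A row gap, outer rows necessarily have a somewhat larger arc
  spacing; the radius remains configurable for geometries with other
  conventions.
* **Array** (`place_array_assembly()`): `nx x ny` anchors at exact grid
  nodes (default pitch 60 A) in the z = 0 plane; chains grow into the +z
  half-space.
* **Bath** (`place_bath_assembly()`): chain seeds placed uniformly at
  random in a periodic box (default edge 725 A), minimum-image convention
  for all inter-chain distances.  An excluded-volume packing estimate
  refuses clearly infeasible densities up front.  (Published box sizes
  for such systems vary between 725 and 755 A between sources; the edge
  length is a parameter.)

The cysteine-gold surface chemistry is abstracted to a rigid anchor
constraint on the C-terminal residue; `append_cys = 5` reproduces the
614-residue construct geometrically.  In multi-chain SAW generation,
chains are grown sequentially in randomized order, each seeing all
previously grown chains as obstacles, to avoid systematic bias toward
early chains.

## Bundle analysis

`build_contact_graph()` connects two residues of *different* chains when
their distance is strictly below 6 A ("shorter than", so ties at exactly
6 A are non-contacts).  Residue-residue distance is the minimum over the
residues' beads (reducing to the backbone-bead distance in the
single-bead model).  For every contact edge, the immediate sequence
neighbours (+-1) of its two endpoints are joined to those endpoints by
adjacency edges.  This augmentation is applied **once**, not
transitively: applied transitively it would chain along the whole
sequence, merging every chain into one component and destroying the
bundle/cross-link distinction.  Connected components are computed with
igraph; components spanning at least two distinct chains are **bundles**,
their **thickness** being the number of distinct chains involved.  All
remaining residues -- isolated ones and single-chain components -- form the
**cross-linking region**.  A cross-link *event* is a maximal
crosslink-labelled run of one chain whose two flanking residues both
belong to bundles (possibly the same bundle).

Two conventions were genuinely open and are settled as follows (both
switchable):

* Thickness histograms are normalized per frame before averaging over the
  trailing analysis window, so every frame carries equal weight
  (`average = "pooled"` pools raw counts instead).
* Bundlehood is defined purely by graph connectivity; the qualitative
  notion of a "linearly arranged, parallel" cluster is reported as a
  descriptive anisotropy score (leading eigenvalue fraction of the bundle
  coordinate covariance) but never used as a filter.

In amino-acid propensities, F and G are split by motif membership:
`F*`/`G*` count phenylalanines and glycines outside any FG/FxFG motif,
while the `FG` and `FxFG` categories collect the motif F and G residues;
the `x` of FxFG is counted in its own amino-acid category.  Motifs are
annotated by a left-to-right non-overlapping scan in which FxFG takes
precedence over FG at the same locus (so GLFG is reported as an FG at its
third position).

## Pore characterization

`build_clearance_grid()` maps the frame onto a cubic lattice (default
spacing 2 A, about half a coarse-grained bead radius) and stores at each
node the exact distance to the nearest bead -- the radius of the largest
sphere that can sit there without steric clash.  The default "point"
clearance follows the literal nearest-bead-distance definition; a
"subtract" mode removes per-bead radii for physical realism.  The pore
size is the maximum over source-to-sink lattice paths of the minimum
clearance along the path, computed by a Dijkstra variant with a max-heap
on the best-known bottleneck value (`widest_bottleneck_path()`); ties
break on node index so witness paths are reproducible.  Choices:

* **6-connectivity by default**: a sphere moving between face-adjacent
  nodes stays within the clearance bound up to a spacing-limited error;
  26-connectivity is available but optimistic at corners (it can only
  widen the result, an inequality the tests assert).
* **Accuracy is one lattice spacing** and is reported alongside every
  result.
* **Domain walls.**  For bath frames the lattice spans the box.  For
  other frames it spans the bead bounding box plus one margin layer; in
  axial probing the transverse margin layers are excluded from paths so
  the probe cannot trivially walk around the structure, and in radial
  probing (ring geometries: source core of radius one quarter of the ring
  inner radius, sink outside the outermost bead) the z margins are
  excluded so the probe cannot escape over the top.

`pore_size_stats()` reports per-frame bottleneck radii with mean and
sample standard deviation over the trailing window, and
`export_pore_map()` writes all nodes above a clearance threshold (default
35 A, i.e. pores admitting a 7 nm sphere) as PDB pseudo-atoms.

## SASA

`shrake_rupley_sasa()` uses golden-spiral sphere-point quadrature
(default 960 points; doubling changes fixture results by well under
0.5%).  Coarse-grained bead radii default to 2.3 A with a 2.6 A probe
(a coarse-grained water bead); both are parameters, because published
coarse-grained SASA analyses rarely print them -- consequently absolute
SASA values are not comparison targets here, only relative statements
such as the bundle-versus-crosslink accessibility contrast of motif
phenylalanines, which the tests assert as an inequality on constructed
fixtures.  The "first phenylalanine" of a motif is the residue at the
motif start index (the F itself for FG, the first F for FxFG).

## Synthetic ground truth: what it does and does not show

The generators in this package plant structures whose analysis outcome is
known by construction: parallel straight chains on a hexagonal lattice
(pitch below/above the contact cutoff toggles bundlehood), cross-link
chains that run inside one bundle, traverse free space above all bundles
with a guaranteed clearance margin, and descend into another bundle, and
channel phantoms whose walls are built from beads (pitch 2 A) so the pore
algorithm is exercised through exactly the same code path as real
frames.  Slab phantoms are grid-aligned so the planted clearance at the
hole centre is exact, including the solid-wall (radius 0) case; the
cylindrical-shell phantom cannot align with a cubic lattice, so its
recovery is exact only to within one spacing.  Truth labels use the same
(chain id, residue index) addressing as the analyses and encode the
adjacency-absorption rule, so comparisons are plain set equalities.

These fixtures validate the *machinery* -- graph construction, component
labelling, widest-path search -- exactly.  They deliberately do not mimic
relaxed molecular-dynamics bead densities, force-field bead types, or
entangled conformations; conclusions about real assemblies additionally
require simulated or experimental structures, which enter through the
PDB/XYZ readers.  Freshly generated SAW assemblies respect the 8 A
excluded-volume rule by construction and therefore contain no 6 A
contacts at all: bundles are a product of relaxation dynamics, not of the
initial-state generator, and the bundle analysis on generated initial
states correctly reports none.

## Numerical choices and degenerate inputs

* Strict inequalities at both cutoffs (6 A contact, 8 A clash), matching
  their verbal definitions; ties are non-contacts.
* SAW bond lengths are exact to 1e-6 A and bend angles to 1e-4 degrees by
  construction; the constraint suite asserts these bounds over 50 chains
  of 100 residues.
* Empty frames are legal: clearance grids cap at the domain diagonal
  (requiring an explicit domain when no box is present), PDB files with
  zero chains round-trip, and SASA of an empty frame is an empty table.
* An isolated residue (no edges) belongs to the cross-linking region;
  `find_components()` excludes it, `decompose_bundles()` labels it.
* Coordinates beyond the PDB fixed-column range raise an explicit error
  rather than truncating silently; frames with more than 62 chains (the
  PDB chain-id alphabet) split across files with a `_partNN` suffix.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
structures at deliberately small scale: 50 SAW chains of 100 residues
for the constraint suite, 25 random lattices of 8-12 nodes per side for
the widest-path oracle, 25 randomized cross-linked brushes, channel
phantoms at 5-40 A radius, and demonstration assemblies of 6-9 chains of
60-80 residues.  Full-scale systems (120 chains of 609-614 residues,
725 A boxes) use exactly the same code paths; the builders and analyses
scale to them, and all size parameters are exposed.

## Known limitations

* The bundle analysis identifies connectivity, not geometry: a bundle's
  "parallelism" is reported descriptively, never enforced.
* SASA ignores periodic images (relevant only for bath frames with
  chains near the box boundary).
* Pore analysis is purely geometric -- the size limit of a passing
  sphere -- with no energetics or diffusion.
* The radial probe assumes the ring axis is z through the origin.
* Secondary structure, hydrogen bonding and all-atom detail are out of
  scope for a one-bead-per-residue model.

## A minimal session

```{r example, eval = FALSE}
# a small tethered brush, its bundles and its pore
arr <- place_array_assembly(3, 3, grid_spacing = 60, mode = "saw",
                            sequence = synthetic_fg_sequence(80), seed = 1)
brush_height(arr)$mean
dec <- decompose_bundles(arr, cutoff = 6)
axial_pore_size(arr, spacing = 2)$bottleneck_radius

# planted validation
cb <- make_crosslinked_brush(
  list(list(k_chains = 3, n_residues = 20, center = c(0, 0)),
       list(k_chains = 2, n_residues = 20, center = c(60, 0))),
  list(list(from = 1, to = 2)))
identical(decompose_bundles(cb$frame)$crosslink_events,
          cb$truth$crosslink_events)
```
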