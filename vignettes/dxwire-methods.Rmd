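---
title: "dxwire: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dxwire: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxwire)
```

## The design problem

A wireframe DNA origami renders a closed polyhedral surface in DNA: every
mesh edge becomes a bundle of parallel duplexes, a single circular
single-stranded scaffold runs through the whole object, and short
synthetic staples hybridize to it to fold the target shape.  `dxwire`
implements the two-helix-bundle (DX) edge variant with continuous edge
lengths and arbitrary vertex angles: edges need not be multiples of a
helical turn, and vertices need not be regular.

## Geometric model and its assumptions

The B-form duplex is modelled as a rigid rod: rise 0.332 nm/bp, 10.5
bp/turn, 2.0 nm diameter.  The two duplexes of an edge are straight,
antiparallel, offset symmetrically by 2.25 nm along the local
face-bisector normal, and span the full quantized edge length centred on
the edge.  Twist accumulates linearly along each duplex; no twist
correction, bending, or electrostatics is modelled.  These
simplifications are standard for top-down wireframe design; downstream
coarse-grained or atomistic simulation is the intended refinement path.

Two printed constants pin the length scale: a 42-bp edge is 13.94 nm,
fixing 0.332 nm/bp.  The companion printed pair (210 bp, 71.06 nm)
implies 0.3384 nm/bp, inconsistent with the first; we adopt 0.332 nm/bp
throughout (it is also the canonical average B-form rise) and note the
discrepancy rather than split the difference.

## Scaffold routing

With all faces wound consistently outward, assigning each duplex of an
edge to one incident face and running its scaffold strand in that face's
winding direction makes the crossover-free scaffold close into one loop
per face.  A scaffold double crossover at the midpoint of an edge merges
the two adjacent face loops.  The complement of a spanning tree of the
mesh graph is, on a genus-0 surface, a spanning tree of the dual (face)
graph, so placing crossovers on exactly the non-tree edges merges all
face loops into one Eulerian cycle.  The implementation never trusts
this argument: it walks the final base-level links and raises a routing
error unless a single cycle of exactly 2·Σ edge_bp paired nucleotides
comes back.

The spanning tree is Prim's algorithm from vertex 1 with deterministic
tie-breaks (shorter edge in bp, then lower far-vertex index, then lower
edge id).  Any spanning tree yields a valid routing; determinism, not
optimality, is the requirement.

**Vertex bridges.** Where the scaffold leaves one duplex and enters the
next, the helix ends are laterally offset (inter-helix spacing, vertex
angle) — the scaffold bridges the gap with unpaired nucleotides,
`n = round(gap_nm / 0.42)`, using 0.42 nm as the single-stranded DNA
contour length per nucleotide.  The source method states the purpose of
these unpaired bases but no constant; 0.42 nm/nt is a standard ssDNA
contour estimate, and the value is exposed in `dx_constants()`.

**Scaffold selection.** M13mp18 (7,249 nt) for required lengths
≤ 7,249; Lambda (48,502 nt) for ≤ 48,502; otherwise a seeded uniform
random sequence of exactly the required length.  The stated rules leave
exactly 7,250 and 48,503 nt formally unassigned; we close the gaps
upward (7,250 → Lambda, 48,503 → random).  The seam (sequence start) is
placed at the first scaffold node of the lowest-index edge — any
deterministic convention works, none is stated.  A circular scaffold
cannot be truncated, so excess length is kept as one unstructured loop
at the seam vertex; it is laid out as a compact helical coil (15 nm
radius, 2.5 nm pitch) anchored just outside the vertex, purely so the
all-atom model stays inside the PDB coordinate box — the coil is an
explicit non-physical placeholder, reported in the design summary.

## Staple rules

The staple motif is parameterized, declared here rather than inferred
from any binary:

* vertex staple domains: terminal 11 bp of each duplex abutting a
  vertex (10 selectable), giving 22-nt staples that cross exactly one
  vertex;
* edge staples: interior divided by antiparallel double crossovers into
  segments — interior segments exactly 21 bp (two turns), the two
  terminal segments absorb the remainder (10–20 bp each), never the
  interior ones, so interior crossover spacing stays exact;
* closed interior segment loops are opened by a nick at the midpoint of
  their helix-1 domain, ≥ 5 bp (in practice ≥ 10) from any crossover;
* staple lengths stay in [20, 60] nt; the shortest legal edge is 42 bp
  (11 + 20 + 11), which coincides with the lower bound on the
  user-specifiable minimum edge length.

Staple sequences are the reverse complement of the scaffold bases they
tile, read 5'→3'; the tiling covers every paired scaffold base exactly
once, which the tests verify per fixture.

## All-atom model

Each paired base receives template atoms rigidly transformed by its
base-pair frame (origin on the helix axis, twist = index · 360/10.5°).
The bundled templates are a **synthetic idealization**: the authentic
average B-form parameter set was not obtainable in this environment, so
heavy-atom nucleotide geometry was taken from public chemical-component
ideal coordinates, planarized, Watson–Crick paired by least squares
against canonical hydrogen-bond distances (plus the 10.85 Å C1'–C1'
separation), and given a single shared sugar-phosphate backbone pose
optimized so that stacked pairs form a 1.60 Å O3'–P contact and a
duplex of any sequence is clash-free above 2.4 Å.  The construction
scripts ship under `tools/`; the package only applies rigid transforms
to the frozen CSV.

Unpaired nucleotides are interpolated with a cubic Bézier: control
handles of length |P3−P0|/3 along the flanking helix tangents (the
curve degenerates to the chord when the tangents are collinear), and
nucleotide *k* of *n* anchored at parameter *k*/(n+1) — uniform in
parameter, not arclength, for simplicity; the difference is a small
redistribution along strongly bent spans.  Orientation along the span
follows the curve tangent with the discrete curvature vector as
in-plane reference, which keeps the output equivariant under rigid
motions of the input mesh.

**Clashes.** The clash detector reports atom pairs below 2.0 Å from
different nucleotides, excluding the covalent backbone neighbourhood —
strand-linked nucleotides and adjacent rungs of the same helix side
(which covers nick-abutting staple termini whose backbone is
geometrically continuous).  Full designs report substantial clash
counts concentrated at vertices: the duplexes span their full edge
length, so at sharp vertices the terminal base pairs of converging
edges interpenetrate, and the Bézier-placed single strands are not
energy minimized.  This is the faithful output of the geometric model;
minimization is explicitly downstream.

## Exports

PDB files use the fixed-column v3.3 layout with the hybrid base-36
numbering beyond the base-10 ceilings (99,999 atoms, 9,999 residues per
chain): one case-sensitive alphabetical character (A–Z then a–z)
followed by base-36 digits (0–9 then A–Z).  The digit orderings are our
declared convention — the sizes (52, 36) are fixed by the scheme, the
orderings are not stated anywhere; the boundary examples
`100000 → A0000` and `10000 → A000` are normative for this artifact.
Chains cycle through the 62 case-sensitive alphanumeric identifiers
with a sidecar strand map when a design exceeds 62 strands.

The caDNAno document places the two duplexes of edge *k* at column
*k−1*, rows 0/1, numbers chosen so the even-numbered helix carries the
scaffold in increasing position and number parity equals (row+col)
parity; arrays are padded to a multiple of 21; vertex unpaired runs
become `loop` insertions at the exiting duplex terminus.  The cylinder
model writes each duplex as a 2 nm diameter prism in ASCII PLY with
per-cylinder metadata in comments.

## The fixture generator

The bundled geometries (tetrahedron, cube, octahedron, icosahedron,
pentagonal bipyramid) stand in for a larger catalogue of pre-defined
targets and exercise triangular and quadrilateral faces, degree-3 to
degree-5 vertices, and unequal edge classes.  `asymmetric_octahedron`
emulates the experimentally demonstrated irregular object: regular
octahedron vertices perturbed by seeded uniform noise of ±15% of the
edge length per coordinate, which at a 63-bp minimum edge yields twelve
pairwise distinct quantized edge lengths and irregular vertex angles
(enforced; the generator redraws from a derived seed on collision).
What a green test on these fixtures establishes: the combinatorial and
geometric invariants of routing, tiling and export on closed genus-0
meshes of modest size.  What it does not: folding yields, mechanical
rigidity, or behaviour on very large meshes, open 2D sheets (out of
scope), or meshes with degenerate/near-collinear faces.

## Numerical choices and degenerate inputs

* Edge quantization rounds half to even (R's `round`), making the
  bp assignment deterministic and unbiased at .5 boundaries.
* Meshes are treated as relative geometry; absolute scale comes only
  from `min_edge_bp` ∈ [42, 210] (bounds checked).
* Binary PLY is rejected with a clear error; face windings are
  repaired by adjacency propagation plus a signed-volume outward check,
  so inconsistent input windings are tolerated.
* Disconnected meshes, vertices in no face, and non-manifold edges are
  hard validation errors — each would make scaffold routing impossible.
* A zero-length Bézier span (coincident endpoints) legally collapses
  all anchors to the endpoint.
* All randomness (asymmetric fixture, random scaffold) flows through
  explicit integer seeds; repeated runs are byte-identical, which the
  tests assert on whole output bundles.

## Known limitations

* Six-helix-bundle edges and 2D (open-sheet) designs are out of scope;
  `edge_type = "dx"` is the documented extension point.
* Duplexes span their full edge length, so vertex regions of sharp
  polyhedra show large reported clash counts (see above); no energy
  minimization or sequence optimization is performed.
* The bundled scaffold records and base templates are synthetic
  stand-ins (correct lengths and idealized geometry, not the authentic
  sequences/parameter set); files and docs are labelled accordingly.
* caDNAno output follows the documented subset of the format (vstrands,
  4-tuples, loops, skips, colors); exotic editor features (insertions
  on staples, multi-document files) are not emitted.
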