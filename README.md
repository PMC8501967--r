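# dxwire

Top-down sequence design of 3D wireframe DNA origami with two-helix-bundle
(DX) edges, supporting **continuous edge lengths** and **arbitrary vertex
angles**.

## Who this is for

Structural DNA nanotechnologists who want to go from a polygonal mesh to a
foldable design without manual routing: given a closed surface (ASCII PLY
or a bundled fixture) and a minimum edge length in base pairs, `dxwire`
produces everything needed to order staples, edit the design in caDNAno,
and run simulations — staple sequences (CSV), a caDNAno JSON document, a
cylinder model and a routing model (PLY), and an all-atom PDB.

## The method

1. **Geometry.** The mesh is validated (every vertex must pertain to at
   least one face, every edge must be shared by exactly two faces) and
   quantized: the minimum edge length *L*<sub>min</sub> ∈ [42, 210] bp is
   assigned to the shortest edge and all other edges scale
   proportionally, rounded to integer base pairs.  Physical lengths
   follow from the B-form rise, 0.332 nm/bp — a 42-bp edge is 13.94 nm.
2. **Scaffold routing.**  Each edge is realized as two antiparallel
   duplexes (a DX edge).  With consistent outward face windings the
   scaffold would form one loop per face; placing a scaffold double
   crossover at the midpoint of every edge *not* in a spanning tree of
   the mesh graph merges these loops into a single Eulerian cycle — one
   circular scaffold visiting both helices of every edge exactly once
   (2·Σ *n*<sub>e</sub> paired nucleotides, *E* − *V* + 1 crossovers).
   At each vertex, `round(gap/0.42 nm)` unpaired scaffold nucleotides
   bridge the spatial gap between the incoming and outgoing helix ends.
3. **Scaffold sequence.**  M13mp18 for required lengths ≤ 7,249 nt,
   Lambda for ≤ 48,502 nt, a seeded random sequence above that; a
   user-supplied sequence always overrides.  Excess scaffold is kept as
   one unstructured single-stranded loop at the seam vertex.
4. **Staples.**  Vertex staples cover the terminal 11 bp of each duplex
   abutting a vertex and cross to the adjacent edge; edge staples fill
   the interior with antiparallel double crossovers every 21 bp (two
   turns at 10.5 bp/turn), odd remainders absorbed by the terminal
   segments.  Every staple is the Watson–Crick complement of the
   scaffold it tiles; lengths stay within 20–60 nt.
5. **Atomic model.**  Idealized B-form base-pair templates (bundled,
   synthetic; see the vignette) are rigidly transformed onto every base
   position (0.332 nm rise, 360/10.5° twist); unpaired nucleotides are
   interpolated with cubic Bézier curves; steric clashes are detected
   and reported per vertex (not minimized — that is downstream work).
6. **Export.**  PDB output uses a hybrid base-36 numbering beyond the
   fixed-column limits (62 chains, 99,999 atoms, 9,999 residues): serial
   100000 → `A0000`, giving >87 million encodable atoms and >2.4 million
   residues.

## Worked example

Design the bundled irregular octahedron (12 distinct edge lengths,
minimum 63 bp) with automatic scaffold selection:

```r
library(dxwire)
cfg <- design_config("asymmetric_octahedron", min_edge_bp = 63, seed = 1,
                     scaffold = "auto", outdir = "out")
d <- run_design(cfg)
```

or from a shell:

```sh
Rscript -e 'dxwire::dxwire_main()' design \
  --input asymmetric_octahedron --min-edge-bp 63 --seed 1 --out out
```

`out/summary.txt` then reads (excerpt):

```
edges: 12
min_edge_bp: 63
edge_bp: 79 101 91 100 88 63 75 102 67 85 82 97
total_paired_nt: 2060
total_unpaired_nt: 81
required_scaffold_nt: 2141
scaffold_name: M13mp18
scaffold_crossovers: 7
staple_count: 67
staple_length_range: 20 42
atoms: 190813
```

Reading it: the twelve edges quantize to twelve *distinct* base-pair
lengths (the irregular geometry), pairing 2·Σ *n*<sub>e</sub> = 2060
scaffold nucleotides; 81 unpaired nucleotides bridge the vertices, so a
2,141-nt scaffold is required — within M13mp18's 7,249 nt, hence the
automatic choice (the remainder is kept as an excess loop).  The
scaffold crosses over on the 7 non-tree edges (*E* − *V* + 1 = 12 − 6 +
1), and 67 staples (24 vertex + 43 edge) tile the paired scaffold
exactly.  The bundle also contains `staples.csv`, `cadnano.json` (+
edge↔helix cross-section sidecar), `cylinder_model.ply`,
`routing_model.ply`, `pseudo_atomic.pdb` and `model.pdb`.

## Notes

- The bundled M13mp18/Lambda records and the B-form templates are
  clearly-labelled synthetic stand-ins of the authentic lengths and
  geometry; swap in real genome FASTAs for wet-lab use.
- Only DX (two-helix-bundle) edges are implemented; the `edge_type`
  option is the documented extension point for six-helix-bundle edges.
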