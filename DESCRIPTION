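Package: dxwire
Title: Top-Down Sequence Design of 3D Wireframe DNA Origami with
    Two-Helix-Bundle Edges
Version: 0.1.0
Authors@R:
    person("dxwire", "maintainers", email = "dxwire@example.org",
           role = c("aut", "cre"))
Description: Fully automatic top-down sequence design of 3D wireframe DNA
    origami built from two-helix-bundle (DX) edges with continuous edge
    lengths and arbitrary vertex angles.  A closed polygonal mesh (ASCII
    PLY or a bundled fixture) is quantized to integer base pairs, a single
    circular scaffold is routed through every edge via a spanning tree and
    an Eulerian loop, unpaired scaffold nucleotides bridge the vertex gaps,
    staple oligonucleotides are generated by Watson-Crick complementarity,
    and the design is emitted as staple CSV, caDNAno JSON, a cylinder
    model, a design summary, and an all-atom PDB using a hybrid base-36
    numbering scheme for structures beyond the fixed-column limits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
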