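# shared fixtures: small complete designs, memoized per test session

.cache <- new.env(parent = emptyenv())

exact_scaffold <- function(required_nt, seed = 101L) {
  dxwire:::with_seed(seed, paste(sample(c("A", "C", "G", "T"),
                                        required_nt, replace = TRUE),
                                 collapse = ""))
}

# routed + sequenced + stapled design for a fixture, exact-length scaffold
small_design <- function(name = "tetrahedron", min_edge_bp = 42L,
                         seed = 1L) {
  key <- paste(name, min_edge_bp, seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  mesh <- generate_fixture(name, min_edge_bp = min_edge_bp, seed = seed)
  scaled <- scale_mesh(mesh, min_edge_bp)
  graph <- build_graph(scaled)
  tree <- spanning_tree(graph)
  route <- insert_vertex_gaps(route_scaffold(graph, tree, scaled), scaled)
  sc <- select_scaffold(route$required_scaffold_nt,
                        user_seq = exact_scaffold(
                          route$required_scaffold_nt))
  route <- assign_sequence(route, sc)
  staples <- generate_staples(route, tree, scaled)
  out <- list(mesh = mesh, scaled = scaled, graph = graph, tree = tree,
              route = route, staples = staples)
  .cache[[key]] <- out
  out
}

small_atoms <- function(name = "tetrahedron", min_edge_bp = 42L,
                        seed = 1L) {
  key <- paste("atoms", name, min_edge_bp, seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  d <- small_design(name, min_edge_bp, seed)
  out <- build_atoms(d$staples, d$route$frames)
  .cache[[key]] <- out
  out
}

# ASCII PLY writer used to exercise the parser with hand-made content
write_raw_ply <- function(path, vertices, faces, extra_header = NULL) {
  lines <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(vertices)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", length(faces)),
             "property list uchar int vertex_indices",
             extra_header,
             "end_header",
             apply(vertices, 1, paste, collapse = " "),
             vapply(faces, function(f) paste(c(length(f), f - 1L),
                                             collapse = " "),
                    character(1)))
  writeLines(lines, path)
  path
}

tetra_vertices <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}
tetra_faces <- function() {
  list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
}
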