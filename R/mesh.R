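#' Construct and validate a wireframe mesh
#'
#' A `dx_mesh` holds the vertices and faces of a closed polygonal surface
#' together with the derived set of unique edges.  Validation enforces the
#' requirements of scaffold routing: every face index is valid, every
#' vertex belongs to at least one face (otherwise the scaffold cannot be
#' routed through it), every edge is shared by exactly two faces (closed
#' manifold), all faces have at least three vertices, and the surface is
#' connected.  Face windings are repaired to a consistent outward
#' orientation by adjacency propagation followed by a signed-volume check;
#' the outward orientation is what later places the two helices of each DX
#' edge on their correct face sides.
#'
#' @param vertices numeric matrix, one row per vertex, columns x,y,z
#'   (relative mesh units; absolute scale is set later by [scale_mesh()]).
#' @param faces list of integer vectors of 1-based vertex indices, each
#'   face wound counter-clockwise when viewed from outside (repaired if
#'   inconsistent).
#' @param name optional label carried through reports.
#' @return An object of class `dx_mesh`: list with `vertices`, `faces`,
#'   `edges` (two-column matrix, smaller index first, ordered
#'   lexicographically), and `name`.
#' @export
dx_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    dx_stop("vertices must be an n x 3 matrix", "dx_validation_error")
  if (!is.list(faces) || length(faces) == 0L)
    dx_stop("faces must be a non-empty list", "dx_validation_error")
  faces <- lapply(faces, as.integer)

  nv <- nrow(vertices)
  for (f in faces) {
    if (length(f) < 3L)
      dx_stop("face with fewer than 3 vertices", "dx_validation_error")
    if (anyNA(f) || any(f < 1L) || any(f > nv))
      dx_stop("face references an invalid vertex index",
              "dx_validation_error")
    if (anyDuplicated(f))
      dx_stop("face repeats a vertex", "dx_validation_error")
  }

  used <- sort(unique(unlist(faces)))
  missing <- setdiff(seq_len(nv), used)
  if (length(missing) > 0L)
    dx_stop(sprintf(
      "vertex %s not referenced by any face; every vertex must pertain to at least one face",
      paste(missing, collapse = ", ")), "dx_validation_error")

  faces <- repair_winding(vertices, faces)
  edges <- derive_edges(faces)
  if (!mesh_connected(nv, edges))
    dx_stop("mesh is disconnected", "dx_validation_error")

  structure(list(vertices = vertices, faces = faces, edges = edges,
                 name = name), class = "dx_mesh")
}

# unique undirected edges from face loops; errors on non-manifold edges
derive_edges <- function(faces) {
  a <- unlist(lapply(faces, function(f) f))
  b <- unlist(lapply(faces, function(f) c(f[-1L], f[1L])))
  key <- paste(pmin(a, b), pmax(a, b))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad) > 0L)
    dx_stop(sprintf("non-manifold edge(s) shared by != 2 faces: %s",
                    paste(bad, collapse = "; ")), "dx_validation_error")
  uk <- !duplicated(key)
  e <- cbind(pmin(a, b)[uk], pmax(a, b)[uk])
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("v1", "v2"))
  e
}

mesh_connected <- function(nv, edges) {
  seen <- logical(nv)
  seen[1L] <- TRUE
  queue <- 1L
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[as.character(v)]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# orient all faces consistently by adjacency propagation, then flip the
# whole surface if the signed volume says the normals point inward
repair_winding <- function(vertices, faces) {
  nf <- length(faces)
  # map directed edges to face ids
  face_of <- list()
  dir_edges <- lapply(faces, function(f) {
    cbind(f, c(f[-1L], f[1L]))
  })
  key_undir <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_faces <- new.env(hash = TRUE)
  for (i in seq_len(nf)) {
    de <- dir_edges[[i]]
    for (j in seq_len(nrow(de))) {
      k <- key_undir(de[j, 1L], de[j, 2L])
      edge_faces[[k]] <- c(edge_faces[[k]], i)
    }
  }
  oriented <- rep(NA, nf)
  oriented[1L] <- TRUE           # keep face 1 as stored
  flip <- logical(nf)
  queue <- 1L
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    f <- faces[[i]]
    if (flip[i]) f <- rev(f)
    de <- cbind(f, c(f[-1L], f[1L]))
    for (j in seq_len(nrow(de))) {
      k <- key_undir(de[j, 1L], de[j, 2L])
      others <- setdiff(edge_faces[[k]], i)
      for (o in others) {
        if (!is.na(oriented[o])) next
        fo <- faces[[o]]
        deo <- cbind(fo, c(fo[-1L], fo[1L]))
        # consistent orientation: neighbour must traverse the shared edge
        # in the opposite direction
        same_dir <- any(deo[, 1L] == de[j, 1L] & deo[, 2L] == de[j, 2L])
        flip[o] <- same_dir
        oriented[o] <- TRUE
        queue <- c(queue, o)
      }
    }
  }
  faces <- lapply(seq_len(nf), function(i)
    if (flip[i]) rev(faces[[i]]) else faces[[i]])
  # outward check: signed volume of the polyhedron must be positive
  vol <- 0
  for (f in faces) {
    p0 <- vertices[f[1L], ]
    for (j in 2:(length(f) - 1L)) {
      vol <- vol + det(rbind(p0, vertices[f[j], ], vertices[f[j + 1L], ])) / 6
    }
  }
  if (vol < 0) faces <- lapply(faces, rev)
  faces
}

#' @export
print.dx_mesh <- function(x, ...) {
  cat(sprintf("dx_mesh '%s': %d vertices, %d edges, %d faces (V-E+F = %d)\n",
              x$name, nrow(x$vertices), nrow(x$edges), length(x$faces),
              nrow(x$vertices) - nrow(x$edges) + length(x$faces)))
  invisible(x)
}
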