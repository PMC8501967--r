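#' Build the design graph of a scaled mesh
#'
#' The design graph has the mesh vertices as nodes and the mesh edges as
#' arcs, each annotated with its base-pair length and its two incident
#' faces.  For every vertex the incident edges are stored in cyclic order,
#' derived from the face loops around the vertex; scaffold and staple
#' traversals at vertices follow this order.
#'
#' @param scaled a [scale_mesh()] result.
#' @return Object of class `dx_graph`: list with `n_nodes`, `arcs`
#'   (data.frame: edge id, v1, v2, bp, face1, face2) and `cyclic`
#'   (per-vertex list of edge/face incidence in rotational order).
#' @export
build_graph <- function(scaled) {
  mesh <- scaled$mesh
  edges <- mesh$edges
  ne <- nrow(edges)
  ekey <- paste(edges[, 1L], edges[, 2L])
  eid_of <- function(a, b) match(paste(pmin(a, b), pmax(a, b)), ekey)

  # two incident faces per edge
  face1 <- integer(ne); face2 <- integer(ne)
  for (fi in seq_along(mesh$faces)) {
    f <- mesh$faces[[fi]]
    ids <- eid_of(f, c(f[-1L], f[1L]))
    for (e in ids) {
      if (face1[e] == 0L) face1[e] <- fi else face2[e] <- fi
    }
  }

  # per-vertex rotational order of incident edges: walk around the vertex
  # face by face (corner of face f at v is bounded by two incident edges)
  nv <- nrow(mesh$vertices)
  cyclic <- vector("list", nv)
  for (v in seq_len(nv)) {
    inc <- which(edges[, 1L] == v | edges[, 2L] == v)
    # corner map: for each incident face, the pair of incident edges at v
    corners <- list()
    for (fi in unique(c(face1[inc], face2[inc]))) {
      f <- mesh$faces[[fi]]
      pos <- match(v, f)
      if (is.na(pos)) next
      nxt <- f[pos %% length(f) + 1L]
      prv <- f[(pos - 2L) %% length(f) + 1L]
      corners[[as.character(fi)]] <- c(eid_of(prv, v), eid_of(v, nxt))
    }
    # chain corners: edge shared by two corners links them
    e0 <- inc[1L]
    order_e <- e0
    repeat {
      last <- order_e[length(order_e)]
      nxt <- NA_integer_
      for (cn in corners) {
        if (cn[1L] == last && !(cn[2L] %in% order_e)) { nxt <- cn[2L]; break }
        if (cn[2L] == last && !(cn[1L] %in% order_e)) { nxt <- cn[1L]; break }
      }
      if (is.na(nxt)) break
      order_e <- c(order_e, nxt)
    }
    if (length(order_e) != length(inc))
      dx_stop(sprintf("vertex %d: could not order incident edges", v),
              "dx_routing_error")
    cyclic[[v]] <- order_e
  }

  arcs <- data.frame(edge = seq_len(ne), v1 = edges[, 1L], v2 = edges[, 2L],
                     bp = scaled$edge_bp, face1 = face1, face2 = face2)
  structure(list(n_nodes = nv, arcs = arcs, cyclic = cyclic,
                 scaled = scaled), class = "dx_graph")
}

#' Deterministic spanning tree of the design graph
#'
#' Prim's algorithm grown from vertex 1, with ties broken first by the
#' shorter base-pair edge length and then by the lower index of the far
#' vertex.  Scaffold crossovers are later placed on every edge *not* in
#' this tree, which by mesh/dual duality yields a single Eulerian scaffold
#' loop.
#'
#' @param graph a [build_graph()] result.
#' @return Object of class `dx_tree`: list with `arcs` (integer edge ids in
#'   the tree) and `root` (vertex 1).
#' @export
spanning_tree <- function(graph) {
  arcs <- graph$arcs
  nv <- graph$n_nodes
  in_tree <- logical(nv)
  in_tree[1L] <- TRUE
  chosen <- integer(0L)
  while (sum(in_tree) < nv) {
    cand <- which(xor(in_tree[arcs$v1], in_tree[arcs$v2]))
    if (length(cand) == 0L)
      dx_stop("graph is disconnected", "dx_routing_error")
    far <- ifelse(in_tree[arcs$v1[cand]], arcs$v2[cand], arcs$v1[cand])
    ord <- order(arcs$bp[cand], far, cand)
    pick <- cand[ord[1L]]
    chosen <- c(chosen, pick)
    in_tree[ifelse(in_tree[arcs$v1[pick]], arcs$v2[pick],
                   arcs$v1[pick])] <- TRUE
  }
  structure(list(arcs = sort(chosen), root = 1L), class = "dx_tree")
}
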