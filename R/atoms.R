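# template cache for the bundled synthetic B-form pair geometry
.dx_env <- new.env(parent = emptyenv())

#' Load the bundled idealized B-form nucleotide templates
#'
#' Heavy-atom base-pair templates in the pair frame (coordinates in
#' Angstroms; x/y in the base-pair plane, +z = scaffold 5'->3' direction).
#' The templates are a synthetic idealization built from public chemical
#' component geometry, Watson-Crick paired against canonical hydrogen-bond
#' distances — a documented stand-in for an average B-form parameter set.
#' One template pair exists per scaffold base letter; `scaffold` is the
#' nucleotide on the scaffold strand, `partner` its complement on the
#' staple strand.
#'
#' @return Named list (A, C, G, T), each with `scaffold` and `partner`
#'   data.frames (residue, atom, element, x, y, z).
#' @export
load_templates <- function() {
  if (!is.null(.dx_env$templates)) return(.dx_env$templates)
  path <- system.file("extdata", "bform_templates_synthetic.csv",
                      package = "dxwire")
  if (!nzchar(path))
    dx_stop("bundled base templates not found", "dx_geometry_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$scaffold_base), function(d) {
    list(scaffold = d[d$role == "scaffold",
                      c("residue", "atom", "element", "x", "y", "z")],
         partner = d[d$role == "partner",
                     c("residue", "atom", "element", "x", "y", "z")])
  })
  .dx_env$templates <- out
  out
}

#' Heavy-atom manifest of the bundled templates
#'
#' @return Named integer vector: atoms per residue (DA, DC, DG, DT).
#' @export
template_manifest <- function() {
  tpl <- load_templates()
  res <- lapply(tpl, function(t) rbind(t$scaffold, t$partner))
  all <- do.call(rbind, res)
  counts <- table(all$residue) / 2L  # each residue appears in two pairs
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Evaluate a cubic Bezier span for unpaired nucleotides
#'
#' Nucleotide k of n is anchored at `B(t_k)`, `t_k = k/(n+1)`, where `B`
#' is the cubic Bezier over the four control points.  Endpoints satisfy
#' `B(0) = P0` and `B(1) = P3` exactly; with collinear handles along the
#' chord the curve degenerates to the straight segment.
#'
#' @param span list with 3-vectors `p0`, `p1`, `p2`, `p3` (nm) and the
#'   nucleotide count `n`.
#' @return `n` x 3 matrix of anchor coordinates (nm), plus unit tangents
#'   as attribute `"tangent"`.
#' @export
interpolate_ssdna <- function(span) {
  n <- span$n
  if (n < 1L) dx_stop("Bezier span needs n >= 1", "dx_bounds_error")
  P <- rbind(span$p0, span$p1, span$p2, span$p3)
  if (any(!is.finite(P))) dx_stop("non-finite control points",
                                  "dx_geometry_error")
  tk <- seq_len(n) / (n + 1)
  bez <- function(t) {
    (1 - t)^3 %o% P[1L, ] + 3 * (1 - t)^2 * t %o% P[2L, ] +
      3 * (1 - t) * t^2 %o% P[3L, ] + t^3 %o% P[4L, ]
  }
  pts <- bez(tk)
  drv <- 3 * (1 - tk)^2 %o% (P[2L, ] - P[1L, ]) +
    6 * (1 - tk) * tk %o% (P[3L, ] - P[2L, ]) +
    3 * tk^2 %o% (P[4L, ] - P[3L, ])
  nrm <- sqrt(rowSums(drv^2))
  tang <- drv / ifelse(nrm > 1e-12, nrm, 1)
  attr(pts, "tangent") <- tang
  pts
}

# control points for a vertex gap: handles of length |P3-P0|/3 along the
# flanking helix tangents (reduces to the chord when tangents are collinear)
bezier_span <- function(p0, p3, t_up, t_dn, n) {
  h <- sqrt(sum((p3 - p0)^2)) / 3
  list(p0 = p0, p1 = p0 + h * t_up, p2 = p3 - h * t_dn, p3 = p3, n = n)
}

#' Build the all-atom structure of a routed, stapled design
#'
#' Strands are reconstructed by following upstream/downstream links: the
#' scaffold from its seam, each staple from its 5' terminus.  Every paired
#' nucleotide receives the template atoms of its base, transformed by the
#' rigid base-pair frame of its duplex position (0.332 nm rise,
#' 360/10.5 degrees twist per index).  Unpaired vertex nucleotides are
#' placed on cubic Bezier curves spanned between the flanking base pairs;
#' excess-loop nucleotides use their precomputed loop coordinates.
#' Coordinates are emitted in Angstroms.
#'
#' @param staples a [generate_staples()] result (carries all base nodes).
#' @param frames the [place_helices()] frames of the design.
#' @return Object of class `dx_atoms`: list with `atoms` (data.table:
#'   serial, strand, strand_role, resseq, residue, atom, element, x, y, z
#'   in Angstroms, node id) and `strands` (per-strand table).
#' @export
build_atoms <- function(staples, frames) {
  nodes <- staples$nodes
  route <- staples$route
  cst <- dx_constants()
  tpl <- load_templates()
  resname <- c(A = "DA", C = "DC", G = "DG", T = "DT")

  # interpolate vertex-gap nucleotides (position NA)
  nodes <- data.table::copy(nodes)
  gap_ids <- nodes$id[is.na(nodes$x) & nodes$role == "scaffold"]
  if (length(gap_ids) > 0L) {
    runs <- split_runs(nodes, gap_ids)
    for (run in runs) {
      a <- nodes$up[run[1L]]
      b <- nodes$down[run[length(run)]]
      pa <- unlist(nodes[a, c("x", "y", "z")])
      pb <- unlist(nodes[b, c("x", "y", "z")])
      ta <- node_tangent(nodes, route, a)
      tb <- node_tangent(nodes, route, b)
      pts <- interpolate_ssdna(bezier_span(pa, pb, ta, tb, length(run)))
      nodes$x[run] <- pts[, 1L]
      nodes$y[run] <- pts[, 2L]
      nodes$z[run] <- pts[, 3L]
    }
  }

  # enumerate strands: scaffold cycle from the seam, then staples
  strands <- list(list(ids = route$order, role = "scaffold"))
  stab <- staples$staples
  for (k in seq_len(nrow(stab))) {
    ids <- integer(stab$length_nt[k])
    cur <- stab$first_node[k]
    for (i in seq_along(ids)) {
      if (is.na(cur)) dx_stop("staple strand broke mid-walk",
                              "dx_topology_error")
      ids[i] <- cur
      cur <- nodes$down[cur]
    }
    if (!is.na(cur)) dx_stop("staple longer than recorded",
                             "dx_topology_error")
    strands[[k + 1L]] <- list(ids = ids, role = "staple")
  }

  fr_pol <- matrix(0L, nrow(route$graph$arcs), 2L)
  for (fr in route$frames$frames) fr_pol[fr$edge, fr$slot] <- 1L
  frame_of <- function(e, slot) get_frame(route$frames, e, slot)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chunks <- vector("list", length(strands))
  for (s in seq_along(strands)) {
    ids <- strands[[s]]$ids
    role <- strands[[s]]$role
    per <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      nid <- ids[i]
      b <- nodes$base[nid]
      if (is.na(b)) dx_stop("unsequenced node during atom build",
                            "dx_topology_error")
      paired <- !is.na(nodes$pair[nid])
      if (paired) {
        key <- if (role == "scaffold") b else comp[[b]]
        part <- if (role == "scaffold") "scaffold" else "partner"
        td <- tpl[[key]][[part]]
        e <- nodes$edge[nid]; slot <- nodes$slot[nid]
        fr <- frame_of(e, slot)
        # base-pair index along the duplex frame (scaffold order)
        idx <- if (role == "scaffold") nodes$spos[nid] - 1L else {
          sc <- nodes$pair[nid]
          nodes$spos[sc] - 1L
        }
        bf <- base_frame(fr, idx)
        xyz <- as.matrix(td[, c("x", "y", "z")]) / 10  # A -> nm
        world <- xyz %*% t(bf$rot) +
          matrix(bf$origin, nrow(td), 3L, byrow = TRUE)
      } else {
        td <- tpl[[b]]$scaffold
        p <- unlist(nodes[nid, c("x", "y", "z")])
        zhat <- ss_tangent(nodes, nid)
        xhat <- ss_normal(nodes, nid, zhat)
        yhat <- cross3(zhat, xhat)
        M <- cbind(xhat, yhat, zhat)
        xyz <- as.matrix(td[, c("x", "y", "z")]) / 10
        world <- xyz %*% t(M) + matrix(p, nrow(td), 3L, byrow = TRUE)
      }
      per[[i]] <- data.table::data.table(
        strand = s, strand_role = role, resseq = i,
        residue = resname[[b]], atom = td$atom, element = td$element,
        x = world[, 1L] * 10, y = world[, 2L] * 10, z = world[, 3L] * 10,
        node = nid)
    }
    chunks[[s]] <- data.table::rbindlist(per)
  }
  atoms <- data.table::rbindlist(chunks)
  atoms$serial <- seq_len(nrow(atoms))

  strand_tab <- data.table::data.table(
    strand = seq_along(strands),
    role = vapply(strands, function(s) s$role, character(1L)),
    n_res = vapply(strands, function(s) length(s$ids), integer(1L)))

  structure(list(atoms = atoms, strands = strand_tab, nodes = nodes,
                 scaled = route$scaled),
            class = "dx_atoms")
}

# contiguous unpaired runs (by downstream linkage) among the given ids
split_runs <- function(nodes, gap_ids) {
  gap <- logical(nrow(nodes))
  gap[gap_ids] <- TRUE
  starts <- gap_ids[!gap[nodes$up[gap_ids]]]
  lapply(starts, function(s) {
    run <- s
    while (gap[nodes$down[run[length(run)]]])
      run <- c(run, nodes$down[run[length(run)]])
    run
  })
}

# 5'->3' direction at a positioned node: the duplex direction for paired
# nodes, the local chain direction for single-stranded ones
node_tangent <- function(nodes, route, nid) {
  if (!is.na(nodes$edge[nid])) {
    fr <- get_frame(route$frames, nodes$edge[nid], nodes$slot[nid])
    return(fr$dir)
  }
  ss_tangent(nodes, nid)
}

# in-plane reference for a single-stranded nucleotide: the discrete
# curvature vector of the chain (rotation-equivariant), falling back to
# an arbitrary perpendicular only for perfectly straight runs
ss_normal <- function(nodes, nid, zhat) {
  a <- nodes$up[nid]; b <- nodes$down[nid]
  pa <- unlist(nodes[a, c("x", "y", "z")])
  pb <- unlist(nodes[b, c("x", "y", "z")])
  p <- unlist(nodes[nid, c("x", "y", "z")])
  v <- pa + pb - 2 * p
  v[!is.finite(v)] <- 0
  v <- v - sum(v * zhat) * zhat
  n <- sqrt(sum(v^2))
  if (n > 1e-9) return(v / n)
  v <- cross3(c(0, 0, 1), zhat)
  if (sqrt(sum(v^2)) < 1e-6) v <- cross3(c(0, 1, 0), zhat)
  v / sqrt(sum(v^2))
}

# local chain direction for a positioned single-stranded nucleotide
ss_tangent <- function(nodes, nid) {
  a <- nodes$up[nid]; b <- nodes$down[nid]
  pa <- unlist(nodes[a, c("x", "y", "z")])
  pb <- unlist(nodes[b, c("x", "y", "z")])
  d <- pb - pa
  n <- sqrt(sum(d^2))
  if (!is.finite(n) || n < 1e-9) c(0, 0, 1) else d / n
}

#' Detect steric clashes in a built structure
#'
#' Reports pairs of atoms closer than `cutoff` that belong to different
#' nucleotides, excluding the covalent backbone neighbourhood (the
#' O3'-P linkage atom sets of consecutive nucleotides).  Bezier-placed
#' single-stranded vertex bridges are not energy-minimized, so clashes
#' concentrate at vertices; the report counts them per nearest vertex.
#'
#' @param structure a [build_atoms()] result.
#' @param cutoff distance in Angstroms (default 2.0).
#' @return List with `pairs` (data.table of clashing atom pairs, each
#'   listed once) and `by_vertex` (counts per nearest mesh vertex).
#' @export
detect_clashes <- function(structure, cutoff = 2.0) {
  if (cutoff <= 0) dx_stop("cutoff must be positive", "dx_bounds_error")
  at <- structure$atoms
  nodes <- structure$nodes
  dt <- data.table::data.table(
    serial = at$serial, node = at$node, name = at$atom,
    x = at$x, y = at$y, z = at$z,
    cx = floor(at$x / cutoff), cy = floor(at$y / cutoff),
    cz = floor(at$z / cutoff))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  res <- vector("list", nrow(offs))
  b <- dt[, .(serial2 = serial, node2 = node, name2 = name,
              x2 = x, y2 = y, z2 = z, cx, cy, cz)]
  data.table::setkey(b, cx, cy, cz)
  for (k in seq_len(nrow(offs))) {
    a <- dt[, .(serial, node, name, x, y, z,
                cx = cx + offs[k, 1L], cy = cy + offs[k, 2L],
                cz = cz + offs[k, 3L])]
    m <- b[a, on = c("cx", "cy", "cz"), nomatch = NULL, allow.cartesian = TRUE]
    m <- m[serial < serial2 & node != node2]
    if (nrow(m) == 0L) next
    m[, d := sqrt((x - x2)^2 + (y - y2)^2 + (z - z2)^2)]
    res[[k]] <- m[d < cutoff]
  }
  pairs <- data.table::rbindlist(res[!vapply(res, is.null, logical(1L))])
  if (nrow(pairs) > 0L) {
    # drop the covalent backbone-link neighbourhood: strand-linked
    # nucleotides, and nucleotides on adjacent rungs of the same helix
    # side (covers nick-abutting staple termini, whose backbones are
    # geometrically continuous)
    dn <- nodes$down
    don <- c("C3'", "O3'", "C2'")
    acc <- c("P", "O5'", "OP1", "OP2")
    bbpair <- (pairs$name %in% don & pairs$name2 %in% acc) |
      (pairs$name2 %in% don & pairs$name %in% acc)
    strand_adj <- dn[pairs$node] == pairs$node2 |
      dn[pairs$node2] == pairs$node
    helix_adj <- nodes$edge[pairs$node] == nodes$edge[pairs$node2] &
      nodes$slot[pairs$node] == nodes$slot[pairs$node2] &
      nodes$role[pairs$node] == nodes$role[pairs$node2] &
      abs(nodes$epos[pairs$node] - nodes$epos[pairs$node2]) == 1L
    linked <- bbpair & (strand_adj | helix_adj)
    linked[is.na(linked)] <- FALSE
    pairs <- pairs[!linked]
  }
  by_vertex <- NULL
  if (nrow(pairs) > 0L) {
    v_nm <- structure$scaled$vertices_nm * 10  # A
    mid <- cbind((pairs$x + pairs$x2) / 2, (pairs$y + pairs$y2) / 2,
                 (pairs$z + pairs$z2) / 2)
    nearest <- apply(mid, 1L, function(p)
      which.min(colSums((t(v_nm) - p)^2)))
    by_vertex <- as.data.frame(table(vertex = nearest),
                               stringsAsFactors = FALSE)
  } else {
    by_vertex <- data.frame(vertex = character(), Freq = integer())
  }
  list(pairs = pairs[, c("serial", "serial2", "node", "node2",
                         "name", "name2", "d")],
       by_vertex = by_vertex,
       n_clashes = nrow(pairs), cutoff = cutoff)
}
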