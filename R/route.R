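#' Route the circular scaffold through every DX edge
#'
#' Every edge is realized as two antiparallel duplex segments of `edge_bp`
#' paired scaffold bases each.  With consistent outward face windings the
#' scaffold strand of the duplex on the side of face *f* travels in *f*'s
#' winding direction, so without crossovers the scaffold would close into
#' one loop per face.  A scaffold double crossover is placed at the
#' midpoint of every edge *not* in the spanning tree; because the non-tree
#' edges form a spanning tree of the dual (face) graph of a closed
#' polyhedral surface, these crossovers merge the face loops into a single
#' Eulerian cycle visiting every duplex segment exactly once.  Tree edges
#' carry no scaffold crossover: there the scaffold runs the full edge on
#' each helix.  The single-loop property is verified, never assumed.
#'
#' @param graph a [build_graph()] result.
#' @param tree a [spanning_tree()] result.
#' @param scaled the [scale_mesh()] result the graph was built from.
#' @return Object of class `dx_route`: list with `nodes` (data.table of
#'   base-level nodes: id, role, base, up, down, pair, edge, slot, face,
#'   epos (1-based position along the edge from its lower vertex), vertex,
#'   x/y/z in nm), `order` (scaffold node ids in cycle order),
#'   `crossovers` (edge ids carrying scaffold crossovers), `corners`
#'   (per-corner transition table), `total_paired_nt`,
#'   `total_unpaired_nt`, `required_scaffold_nt`, plus the `frames` used.
#' @export
route_scaffold <- function(graph, tree, scaled) {
  cst <- dx_constants()
  arcs <- graph$arcs
  ne <- nrow(arcs)
  frames <- place_helices(scaled)

  # allocate scaffold nodes per duplex, ordered along scaffold travel
  n_by_edge <- arcs$bp
  total <- 2L * sum(n_by_edge)
  node_edge <- integer(total); node_slot <- integer(total)
  node_spos <- integer(total)  # 1..n along scaffold travel on the duplex
  first_id <- matrix(0L, ne, 2L)  # id of scaffold-order-first node
  at <- 0L
  for (e in seq_len(ne)) {
    n <- n_by_edge[e]
    for (slot in 1:2) {
      first_id[e, slot] <- at + 1L
      node_edge[(at + 1L):(at + n)] <- e
      node_slot[(at + 1L):(at + n)] <- slot
      node_spos[(at + 1L):(at + n)] <- seq_len(n)
      at <- at + n
    }
  }
  sid <- function(e, slot, spos) first_id[cbind(e, slot)] + spos - 1L

  # within-duplex downstream links
  dn <- rep(NA_integer_, total)
  for (e in seq_len(ne)) {
    n <- n_by_edge[e]
    for (slot in 1:2) {
      ids <- sid(e, slot, seq_len(n))
      dn[ids[-n]] <- ids[-1L]
    }
  }

  # corner links: scaffold leaves duplex(e_prv, f) at v and enters
  # duplex(e_nxt, f); record each corner for vertex-gap insertion
  corners <- corner_table(graph)
  slot_of <- function(e, f) ifelse(arcs$face1[e] == f, 1L, 2L)
  corners$slot_in <- slot_of(corners$edge_in, corners$face)
  corners$slot_out <- slot_of(corners$edge_out, corners$face)
  corners$node_in <- sid(corners$edge_in, corners$slot_in,
                         n_by_edge[corners$edge_in])
  corners$node_out <- sid(corners$edge_out, corners$slot_out, 1L)
  dn[corners$node_in] <- corners$node_out

  # scaffold double crossovers at midpoints of non-tree edges
  xover <- setdiff(seq_len(ne), tree$arcs)
  for (e in xover) {
    n <- n_by_edge[e]
    m <- n %/% 2L
    # duplexes travel in opposite directions; spos j on slot 2 sits at the
    # same physical rung as spos n+1-j on slot 1
    a_m  <- sid(e, 1L, m);      a_m1 <- sid(e, 1L, m + 1L)
    b_nm <- sid(e, 2L, n - m);  b_nm1 <- sid(e, 2L, n - m + 1L)
    dn[a_m] <- b_nm1
    dn[b_nm] <- a_m1
  }

  up <- rep(NA_integer_, total)
  up[dn] <- seq_len(total)
  if (anyNA(dn) || anyNA(up))
    dx_stop("scaffold routing produced open ends", "dx_routing_error")

  # verify the single-loop property
  ord <- integer(total)
  cur <- 1L
  for (i in seq_len(total)) {
    ord[i] <- cur
    cur <- dn[cur]
  }
  if (cur != 1L || anyDuplicated(ord) > 0L)
    dx_stop("scaffold routing did not close into a single loop",
            "dx_routing_error")

  # pairing: scaffold bases of the two duplexes of one edge are paired
  # with staple bases, not with each other; scaffold pair stays NA here.
  # geometric positions from the helix frames
  xyz <- matrix(NA_real_, total, 3L)
  for (fr in frames$frames) {
    ids <- sid(fr$edge, fr$slot, seq_len(fr$bp))
    steps <- (seq_len(fr$bp) - 1L) * cst$rise_per_bp
    xyz[ids, ] <- rep(fr$origin, each = fr$bp) + outer(steps, fr$dir)
  }

  nodes <- data.table::data.table(
    id = seq_len(total), role = "scaffold", base = NA_character_,
    up = up, down = dn, pair = NA_integer_,
    edge = node_edge, slot = node_slot, spos = node_spos,
    epos = ifelse(frames_polarity(frames, node_edge, node_slot) > 0L,
                  node_spos, n_by_edge[node_edge] + 1L - node_spos),
    vertex = NA_integer_,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    staple = NA_integer_)

  structure(list(
    nodes = nodes, order = ord, crossovers = xover, corners = corners,
    total_paired_nt = total, total_unpaired_nt = 0L,
    required_scaffold_nt = total,
    frames = frames, graph = graph, tree = tree, scaled = scaled,
    excess_loop_nt = 0L, start_node = 1L
  ), class = "dx_route")
}

frames_polarity <- function(frames, edge, slot) {
  pol <- vapply(frames$frames, function(f) f$polarity, integer(1L))
  key <- vapply(frames$frames, function(f) paste(f$edge, f$slot),
                character(1L))
  pol[match(paste(edge, slot), key)]
}

# one row per (face, vertex) corner: scaffold transition edge_in -> edge_out
corner_table <- function(graph) {
  mesh <- graph$scaled$mesh
  edges <- mesh$edges
  ekey <- paste(edges[, 1L], edges[, 2L])
  out <- list()
  for (fi in seq_along(mesh$faces)) {
    f <- mesh$faces[[fi]]
    k <- length(f)
    for (j in seq_len(k)) {
      v <- f[j]
      prv <- f[(j - 2L) %% k + 1L]
      nxt <- f[j %% k + 1L]
      out[[length(out) + 1L]] <- data.frame(
        face = fi, vertex = v,
        edge_in = match(paste(min(prv, v), max(prv, v)), ekey),
        edge_out = match(paste(min(v, nxt), max(v, nxt)), ekey))
    }
  }
  do.call(rbind, out)
}

#' Insert unpaired scaffold nucleotides at vertex transitions
#'
#' At every vertex transition between an incoming and an outgoing duplex
#' the scaffold must bridge the spatial gap between the two helix ends
#' (the ends are misaligned because of the lateral helix offsets and the
#' native twist of B-form DNA).  The bridge is built from
#' `round(gap_nm / 0.42)` unpaired scaffold nucleotides (0.42 nm contour
#' length per single-stranded nucleotide); their coordinates stay unset
#' here and are interpolated with a cubic Bezier during atom building.
#'
#' @param route a [route_scaffold()] result.
#' @param scaled the matching [scale_mesh()] result.
#' @return The updated `dx_route` with unpaired nodes spliced in,
#'   refreshed totals, and a `vertex_runs` table (vertex, face, count,
#'   flanking edges).
#' @export
insert_vertex_gaps <- function(route, scaled) {
  cst <- dx_constants()
  nodes <- data.table::copy(route$nodes)
  corners <- route$corners
  gaps <- numeric(nrow(corners))
  for (i in seq_len(nrow(corners))) {
    a <- unlist(nodes[corners$node_in[i], c("x", "y", "z")])
    b <- unlist(nodes[corners$node_out[i], c("x", "y", "z")])
    gaps[i] <- sqrt(sum((a - b)^2))
  }
  counts <- as.integer(round(gaps / cst$ssdna_len_per_nt))
  new_total <- sum(counts)

  if (new_total > 0L) {
    base_id <- nrow(nodes)
    add <- data.table::data.table(
      id = base_id + seq_len(new_total), role = "scaffold",
      base = NA_character_, up = NA_integer_, down = NA_integer_,
      pair = NA_integer_, edge = NA_integer_, slot = NA_integer_,
      spos = NA_integer_, epos = NA_integer_,
      vertex = rep(corners$vertex, counts),
      x = NA_real_, y = NA_real_, z = NA_real_, staple = NA_integer_)
    nodes <- data.table::rbindlist(list(nodes, add))
    at <- base_id
    for (i in seq_len(nrow(corners))) {
      k <- counts[i]
      if (k == 0L) next
      ids <- at + seq_len(k)
      at <- at + k
      a <- corners$node_in[i]; b <- corners$node_out[i]
      chain <- c(a, ids, b)
      for (j in seq_len(length(chain) - 1L)) {
        nodes$down[chain[j]] <- chain[j + 1L]
        nodes$up[chain[j + 1L]] <- chain[j]
      }
    }
  }

  runs <- cbind(corners[, c("vertex", "face", "edge_in", "edge_out")],
                gap_nm = gaps, count = counts)
  route$nodes <- nodes
  route$vertex_runs <- runs
  route$total_unpaired_nt <- new_total
  route$required_scaffold_nt <- route$total_paired_nt + new_total
  route$order <- walk_cycle(nodes, route$start_node,
                            route$required_scaffold_nt)
  route
}

walk_cycle <- function(nodes, start, expect_len) {
  ord <- integer(expect_len)
  cur <- start
  for (i in seq_len(expect_len)) {
    ord[i] <- cur
    cur <- nodes$down[cur]
    if (is.na(cur)) dx_stop("broken scaffold link", "dx_routing_error")
  }
  if (cur != start)
    dx_stop("scaffold loop length mismatch", "dx_routing_error")
  ord
}
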