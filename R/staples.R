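#' Generate the staple set of a routed design
#'
#' Staples tile the strand space complementary to the scaffold.  Two
#' classes are produced per the DX-edge motif:
#'
#' * **vertex staples** — one per face corner: the terminal
#'   `vertex_domain_bp` (default 11) base pairs of the duplex entering the
#'   vertex and of the duplex leaving it, joined by a backbone link across
#'   the vertex (staples carry no unpaired bases; the link simply spans
#'   the vertex).
#' * **edge staples** — the interior of each edge is divided by staple
#'   double crossovers into segments: interior segments of exactly 21 bp
#'   (two helical turns at 10.5 bp/turn) and two terminal segments that
#'   absorb the remainder (widened, never the interior ones).  Each
#'   segment yields one staple covering it on both helices through the
#'   flanking crossovers; closed interior segments are opened by a nick at
#'   the midpoint of their helix-1 domain, at least 5 bp from any
#'   crossover.
#'
#' Every staple base is the Watson-Crick complement of the scaffold base
#' it pairs with; staples tile all paired scaffold bases exactly once.
#'
#' @param route a sequenced route ([assign_sequence()] result).
#' @param tree the [spanning_tree()] used for routing (kept for interface
#'   symmetry; staple tiling itself is independent of the tree).
#' @param scaled the matching [scale_mesh()] result.
#' @param vertex_domain_bp terminal base pairs per duplex claimed by
#'   vertex staples (10 or 11; default 11).
#' @return Object of class `dx_staples`: list with `staples` (data.table:
#'   id, class, residence, length_nt, sequence_5to3, color, first/last
#'   node), `nodes` (all base nodes including staple nodes), `nicks` and
#'   `crossover_pos` tables.
#' @export
generate_staples <- function(route, tree, scaled, vertex_domain_bp = 11L) {
  T_ <- as.integer(vertex_domain_bp)
  if (!(T_ %in% c(10L, 11L)))
    dx_stop("vertex_domain_bp must be 10 or 11", "dx_design_error")
  nodes <- data.table::copy(route$nodes)
  arcs <- route$graph$arcs
  ne <- nrow(arcs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  # fast lookup: scaffold node id by (edge, slot, epos)
  sc_nodes <- nodes[nodes$role == "scaffold" & !is.na(nodes$edge), ]
  skey <- paste(sc_nodes$edge, sc_nodes$slot, sc_nodes$epos)
  sid_of <- stats::setNames(sc_nodes$id, skey)
  scaffold_at <- function(e, slot, epos) unname(sid_of[paste(e, slot, epos)])

  # allocate one staple node per scaffold paired node
  n_st <- nrow(sc_nodes)
  base_id <- nrow(nodes)
  st <- data.table::data.table(
    id = base_id + seq_len(n_st), role = "staple",
    base = unname(comp[sc_nodes$base]),
    up = NA_integer_, down = NA_integer_,
    pair = sc_nodes$id,
    edge = sc_nodes$edge, slot = sc_nodes$slot, spos = NA_integer_,
    epos = sc_nodes$epos, vertex = NA_integer_,
    x = sc_nodes$x, y = sc_nodes$y, z = sc_nodes$z,
    staple = NA_integer_)
  stid_of <- stats::setNames(st$id, paste(st$edge, st$slot, st$epos))
  staple_at <- function(e, slot, epos) unname(stid_of[paste(e, slot, epos)])

  # staple travel direction per duplex in epos terms: opposite of scaffold
  pol <- matrix(0L, ne, 2L)    # scaffold polarity (+1: epos increasing)
  for (fr in route$frames$frames) pol[fr$edge, fr$slot] <- fr$polarity

  paths <- list()    # each: list(class, residence, node ids 5'->3')
  nicks <- list()
  xpos <- list()

  for (e in seq_len(ne)) {
    n <- arcs$bp[e]
    m <- n - 2L * T_
    if (m < 20L)
      dx_stop(sprintf(
        "edge %d too short (%d bp) for staple length constraints", e, n),
        "dx_design_error")
    # segment boundaries of the interior [T+1, n-T]
    cnum <- (m - 20L) %/% 21L + 1L
    r <- m - 21L * (cnum - 1L)
    e1 <- (r + 1L) %/% 2L
    seg_len <- c(e1, rep(21L, cnum - 1L), r - e1)
    seg_hi <- T_ + cumsum(seg_len)
    seg_lo <- seg_hi - seg_len + 1L
    # helix whose scaffold runs epos-increasing ("A"); staple on A runs
    # epos-decreasing, staple on the other helix ("B") runs increasing
    slotA <- if (pol[e, 1L] > 0L) 1L else 2L
    slotB <- 3L - slotA
    for (s in seq_along(seg_len)) {
      lo <- seg_lo[s]; hi <- seg_hi[s]
      idsA <- staple_at(e, slotA, hi:lo)       # epos decreasing
      idsB <- staple_at(e, slotB, lo:hi)       # epos increasing
      if (s == 1L) {
        path <- c(idsB, idsA)                  # B rises to hi, crosses
      } else if (s == length(seg_len)) {
        path <- c(idsA, idsB)                  # A descends to lo, crosses
      } else {
        # closed segment loop opened by a nick mid-way along the A domain
        q <- lo + as.integer(floor((hi - lo) / 2))
        path <- c(staple_at(e, slotA, q:lo), idsB,
                  staple_at(e, slotA, hi:(q + 1L)))
        nicks[[length(nicks) + 1L]] <-
          data.frame(edge = e, slot = slotA, epos = q)
      }
      paths[[length(paths) + 1L]] <-
        list(class = "edge", residence = e, ids = path)
    }
    for (s in seq_len(length(seg_len) - 1L)) {
      xpos[[length(xpos) + 1L]] <-
        data.frame(edge = e, boundary_epos = seg_hi[s])
    }
  }

  # vertex staples: one per corner, entering on the outgoing duplex's
  # staple strand and leaving on the incoming duplex's staple strand
  corners <- route$corners
  for (i in seq_len(nrow(corners))) {
    v <- corners$vertex[i]
    e_in <- corners$edge_in[i];  s_in <- corners$slot_in[i]
    e_out <- corners$edge_out[i]; s_out <- corners$slot_out[i]
    n_in <- arcs$bp[e_in]; n_out <- arcs$bp[e_out]
    # scaffold on (e_out, s_out) leaves v: staple travels toward v.
    # epos of the v end of (e_out): scaffold spos 1 end
    epos_out_v <- if (pol[e_out, s_out] > 0L) 1L else n_out
    dir_out <- if (pol[e_out, s_out] > 0L) 1L else -1L
    span_out <- epos_out_v + dir_out * ((T_ - 1L):0L)  # toward v
    epos_in_v <- if (pol[e_in, s_in] > 0L) n_in else 1L
    dir_in <- if (pol[e_in, s_in] > 0L) -1L else 1L
    span_in <- epos_in_v + dir_in * (0L:(T_ - 1L))     # away from v
    path <- c(staple_at(e_out, s_out, span_out),
              staple_at(e_in, s_in, span_in))
    paths[[length(paths) + 1L]] <-
      list(class = "vertex", residence = v, ids = path)
  }

  # link the nodes of each path and tabulate staples
  palette <- c("#1700de", "#b8056f", "#cc0000", "#f7931e", "#f74308",
               "#57bb00", "#007200", "#03b6a2", "#32b86c", "#333333",
               "#aaaa00", "#888888", "#7300de", "#0066cc", "#aa00aa",
               "#006666")
  ord <- order(vapply(paths, function(p) p$ids[1L], integer(1L)))
  paths <- paths[ord]
  rows <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    ids <- p$ids
    if (anyNA(ids)) dx_stop("staple path hit a missing node",
                            "dx_design_error")
    loc <- ids - base_id
    st$down[loc[-length(loc)]] <- ids[-1L]
    st$up[loc[-1L]] <- ids[-length(loc)]
    st$staple[loc] <- k
    rows[[k]] <- data.table::data.table(
      staple_id = k, class = p$class, edge_or_vertex = p$residence,
      length_nt = length(ids),
      sequence_5to3 = paste(st$base[loc], collapse = ""),
      color = palette[(k - 1L) %% length(palette) + 1L],
      first_node = ids[1L], last_node = ids[length(ids)])
  }
  staples <- data.table::rbindlist(rows)

  # every scaffold paired base must be covered exactly once
  if (anyNA(st$staple))
    dx_stop("staple tiling left uncovered scaffold bases",
            "dx_design_error")

  nodes <- data.table::rbindlist(list(nodes, st))
  nodes$pair[st$pair] <- st$id   # symmetric pairing

  structure(list(
    staples = staples, nodes = nodes,
    nicks = if (length(nicks)) do.call(rbind, nicks) else
      data.frame(edge = integer(), slot = integer(), epos = integer()),
    crossover_pos = unique(do.call(rbind, xpos)),
    vertex_domain_bp = T_,
    route = route
  ), class = "dx_staples")
}

#' Summary statistics of a staple set
#'
#' @param staples a [generate_staples()] result.
#' @return List with a per-staple table (length, class, residence, GC
#'   fraction) and totals (staple count, total nt, length range).
#' @export
staple_statistics <- function(staples) {
  tab <- data.table::copy(staples$staples)
  gc <- vapply(strsplit(tab$sequence_5to3, ""), function(s)
    mean(s %in% c("G", "C")), numeric(1L))
  tab$gc_fraction <- gc
  list(per_staple = tab,
       n_staples = nrow(tab),
       total_nt = sum(tab$length_nt),
       length_range = range(tab$length_nt),
       n_vertex = sum(tab$class == "vertex"),
       n_edge = sum(tab$class == "edge"))
}
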