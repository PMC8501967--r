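#' Export a routed, stapled design as a caDNAno JSON document
#'
#' Every duplex maps to one virtual helix on a honeycomb index grid: the
#' two duplexes of edge *k* (1-based) sit at column *k-1*, rows 0 and 1,
#' with helix numbers 2(k-1) and 2(k-1)+1 assigned so that the
#' even-numbered helix carries the scaffold in the direction of
#' increasing position and the number parity matches the (row+col) parity
#' convention of the honeycomb lattice.  Positions are padded to a
#' multiple of 21.  Scaffold and staple linked lists use the caDNAno
#' 4-tuple convention `[from_helix, from_pos, to_helix, to_pos]` with -1
#' sentinels; unpaired vertex runs become `loop` insertions at the duplex
#' terminus where the scaffold exits into the vertex.  A sidecar CSV
#' (`<path>.crosssection.csv`) maps edge ids to helix numbers.
#'
#' @param staples a [generate_staples()] result.
#' @param path output JSON path.
#' @param name document name.
#' @return `path`, invisibly.
#' @export
write_cadnano <- function(staples, path, name = "dxwire design") {
  route <- staples$route
  nodes <- staples$nodes
  arcs <- route$graph$arcs
  ne <- nrow(arcs)

  # helix bookkeeping: slot with scaffold polarity +1 gets the even number
  pol <- matrix(0L, ne, 2L)
  for (fr in route$frames$frames) pol[fr$edge, fr$slot] <- fr$polarity
  helix_num <- matrix(0L, ne, 2L)   # cadnano num per (edge, slot)
  helix_row <- integer(2L * ne)
  helix_col <- integer(2L * ne)
  for (e in seq_len(ne)) {
    even_slot <- if (pol[e, 1L] > 0L) 1L else 2L
    helix_num[e, even_slot] <- 2L * (e - 1L)
    helix_num[e, 3L - even_slot] <- 2L * (e - 1L) + 1L
    col <- e - 1L
    # parity convention: num %% 2 == (row + col) %% 2
    r_even <- if (col %% 2L == 0L) 0L else 1L
    helix_row[2L * (e - 1L) + 1L] <- r_even            # even num
    helix_row[2L * (e - 1L) + 2L] <- 1L - r_even       # odd num
    helix_col[2L * (e - 1L) + 1L] <- col
    helix_col[2L * (e - 1L) + 2L] <- col
  }

  width <- 21L * as.integer(ceiling((max(arcs$bp) + 42L) / 21L))
  c0 <- 21L    # 0-based first occupied column

  # per-node grid coordinates (paired nodes only)
  paired <- !is.na(nodes$edge)
  node_num <- rep(NA_integer_, nrow(nodes))
  node_col <- rep(NA_integer_, nrow(nodes))
  node_num[paired] <- helix_num[cbind(nodes$edge[paired],
                                      nodes$slot[paired])]
  node_col[paired] <- c0 + nodes$epos[paired] - 1L

  # skip across unpaired runs; returns c(node or NA, run length)
  hop <- function(id, dircol) {
    run <- 0L
    cur <- if (dircol == "down") nodes$down[id] else nodes$up[id]
    while (!is.na(cur) && is.na(node_num[cur])) {
      run <- run + 1L
      cur <- if (dircol == "down") nodes$down[cur] else nodes$up[cur]
    }
    c(cur, run)
  }

  empty4 <- function() rep(list(c(-1L, -1L, -1L, -1L)), width)
  vh <- vector("list", 2L * ne)
  for (h in seq_len(2L * ne)) {
    vh[[h]] <- list(scaf = empty4(), stap = empty4(),
                    loop = integer(width), skip = integer(width),
                    colors = list())
  }

  sc_ids <- which(paired & nodes$role == "scaffold")
  for (id in sc_ids) {
    h <- node_num[id] + 1L
    p <- node_col[id] + 1L
    upn <- hop(id, "up")
    dnn <- hop(id, "down")
    fr <- if (is.na(upn[1L])) c(-1L, -1L) else
      c(node_num[upn[1L]], node_col[upn[1L]])
    to <- if (is.na(dnn[1L])) c(-1L, -1L) else
      c(node_num[dnn[1L]], node_col[dnn[1L]])
    vh[[h]]$scaf[[p]] <- c(fr, to)
    if (dnn[2L] > 0L)   # unpaired run exits here: loop insertion
      vh[[h]]$loop[p] <- vh[[h]]$loop[p] + dnn[2L]
  }

  st_ids <- which(paired & nodes$role == "staple")
  for (id in st_ids) {
    h <- node_num[id] + 1L
    p <- node_col[id] + 1L
    u <- nodes$up[id]
    d <- nodes$down[id]
    fr <- if (is.na(u)) c(-1L, -1L) else c(node_num[u], node_col[u])
    to <- if (is.na(d)) c(-1L, -1L) else c(node_num[d], node_col[d])
    vh[[h]]$stap[[p]] <- c(fr, to)
  }

  # staple colors at 5' ends
  stab <- staples$staples
  for (k in seq_len(nrow(stab))) {
    id <- stab$first_node[k]
    h <- node_num[id] + 1L
    cint <- strtoi(sub("^#", "", stab$color[k]), base = 16L)
    vh[[h]]$colors[[length(vh[[h]]$colors) + 1L]] <-
      c(node_col[id], cint)
  }

  vstrands <- lapply(order(seq_len(2L * ne)), function(h) {
    list(row = helix_row[h], col = helix_col[h], num = h - 1L,
         scaf = vh[[h]]$scaf, stap = vh[[h]]$stap,
         loop = as.list(vh[[h]]$loop), skip = as.list(vh[[h]]$skip),
         stap_colors = vh[[h]]$colors,
         scafLoop = list(), stapLoop = list())
  })
  doc <- list(name = name, vstrands = vstrands)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)

  xsec <- data.frame(edge = rep(seq_len(ne), each = 2L),
                     slot = rep(1:2, ne),
                     helix_num = as.vector(t(helix_num)))
  utils::write.csv(xsec, paste0(path, ".crosssection.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Walk the scaffold linked list of a caDNAno document
#'
#' Follows the `scaf` 4-tuples from a starting occupied position until it
#' returns to the start (or hits a sentinel).  Used to validate that the
#' exported scaffold closes into a single cycle.
#'
#' @param doc parsed caDNAno document (from [jsonlite::read_json()] or
#'   equivalent list).
#' @return Number of steps taken to return to the start, or `NA` if the
#'   walk terminated at a sentinel.
#' @export
cadnano_scaffold_walk <- function(doc) {
  vs <- doc$vstrands
  num_of <- vapply(vs, function(v) as.integer(v$num), integer(1L))
  start <- NULL
  for (v in vs) {
    for (p in seq_along(v$scaf)) {
      t4 <- unlist(v$scaf[[p]])
      if (any(t4 != -1L)) { start <- c(v$num, p - 1L); break }
    }
    if (!is.null(start)) break
  }
  if (is.null(start)) return(NA_integer_)
  cur <- start
  steps <- 0L
  repeat {
    v <- vs[[match(cur[1L], num_of)]]
    t4 <- unlist(v$scaf[[cur[2L] + 1L]])
    nxt <- t4[3:4]
    if (nxt[1L] == -1L) return(NA_integer_)
    steps <- steps + 1L
    if (nxt[1L] == start[1L] && nxt[2L] == start[2L]) return(steps)
    cur <- nxt
    if (steps > 10000000L) return(NA_integer_)
  }
}
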