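#' Select a scaffold sequence for a required length
#'
#' Default selection rule: M13mp18 for required lengths up to and
#' including 7,249 nt; a Lambda phage sequence up to and including
#' 48,502 nt; otherwise a seeded random sequence of exactly the required
#' length.  (Required lengths of exactly 7,250 and 48,503 nt fall between
#' the stated rules; this implementation assigns them to Lambda and to
#' random respectively.)  A user-supplied sequence always overrides the
#' rule.
#'
#' The bundled M13mp18 and Lambda records are seeded random synthetic
#' stand-ins of the authentic lengths (7,249 and 48,502 nt), shipped as
#' `*_synthetic.fa`; swap in the real genome FASTA files for laboratory
#' use.
#'
#' @param required_nt required scaffold length (paired + vertex-unpaired
#'   nucleotides).
#' @param user_seq optional user scaffold: character string of A/C/G/T
#'   letters (or a vector of lines).
#' @param seed integer seed for the random-scaffold branch.
#' @return Object of class `dx_scaffold`: list with `name`, `sequence`,
#'   `length`, `circular`.
#' @export
#' @examples
#' select_scaffold(7249)$name
#' select_scaffold(7250)$name
select_scaffold <- function(required_nt, user_seq = NULL, seed = 1L) {
  cst <- dx_constants()
  required_nt <- as.integer(required_nt)
  if (is.na(required_nt) || required_nt < 1L)
    dx_stop("required_nt must be >= 1", "dx_bounds_error")

  if (!is.null(user_seq)) {
    seq <- toupper(gsub("\\s", "", paste(user_seq, collapse = "")))
    if (grepl("[^ACGT]", seq))
      dx_stop("user scaffold contains letters outside A/C/G/T",
              "dx_alphabet_error")
    if (nchar(seq) < required_nt)
      dx_stop(sprintf("user scaffold too short: %d nt < required %d nt",
                      nchar(seq), required_nt), "dx_scaffold_length_error")
    return(structure(list(name = "user", sequence = seq,
                          length = nchar(seq), circular = TRUE),
                     class = "dx_scaffold"))
  }

  if (required_nt <= cst$m13_len) {
    seq <- read_fasta_seq(scaffold_file("m13mp18_synthetic.fa"))
    name <- "M13mp18"
  } else if (required_nt <= cst$lambda_len) {
    seq <- read_fasta_seq(scaffold_file("lambda_synthetic.fa"))
    name <- "Lambda"
  } else {
    seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"),
                                        required_nt, replace = TRUE),
                                 collapse = ""))
    name <- "random"
  }
  structure(list(name = name, sequence = seq, length = nchar(seq),
                 circular = TRUE), class = "dx_scaffold")
}

scaffold_file <- function(fname) {
  p <- system.file("extdata", fname, package = "dxwire")
  if (!nzchar(p))
    dx_stop(sprintf("bundled scaffold %s not found", fname),
            "dx_scaffold_length_error")
  p
}

# minimal single-record FASTA / plain text reader
read_fasta_seq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^>", lines)]
  toupper(gsub("\\s", "", paste(lines, collapse = "")))
}

#' Write scaffold letters onto the routed nodes
#'
#' Scaffold letters are written in downstream (5'->3') order starting at a
#' deterministic seam: the first scaffold node of the lowest-index edge,
#' or, when `start_vertex` is given, the first duplex node leaving that
#' vertex.  Scaffold nucleotides in excess of the required length cannot
#' be removed from a circular scaffold; they are kept as one unstructured
#' single-stranded loop anchored at the seam vertex (laid out on a circle
#' of matching contour length so that downstream geometry stays
#' non-degenerate) and reported in the design summary.
#'
#' @param route a [insert_vertex_gaps()] result.
#' @param scaffold a [select_scaffold()] result.
#' @param start_vertex optional vertex index for the seam.
#' @return The updated `dx_route` with `base` letters on all scaffold
#'   nodes, `scaffold` metadata, `excess_loop_nt`, and refreshed `order`.
#' @export
assign_sequence <- function(route, scaffold, start_vertex = NULL) {
  if (scaffold$length < route$required_scaffold_nt)
    dx_stop(sprintf("scaffold %s (%d nt) shorter than required %d nt",
                    scaffold$name, scaffold$length,
                    route$required_scaffold_nt),
            "dx_scaffold_length_error")
  nodes <- data.table::copy(route$nodes)
  corners <- route$corners

  start <- if (is.null(start_vertex)) {
    route$start_node
  } else {
    cand <- corners$node_out[corners$vertex == start_vertex]
    if (length(cand) == 0L)
      dx_stop(sprintf("no duplex starts at vertex %s", start_vertex),
              "dx_routing_error")
    min(cand)
  }
  anchor_vertex <- corners$vertex[match(start, corners$node_out)]
  if (is.na(anchor_vertex)) anchor_vertex <- route$scaled$mesh$edges[1L, 1L]

  excess <- scaffold$length - route$required_scaffold_nt
  if (excess > 0L) {
    loop <- excess_loop_nodes(route, nodes, anchor_vertex, excess)
    nodes <- loop$nodes
    # splice between up[start] and start
    prev <- nodes$up[start]
    chain <- c(prev, loop$ids, start)
    for (j in seq_len(length(chain) - 1L)) {
      nodes$down[chain[j]] <- chain[j + 1L]
      nodes$up[chain[j + 1L]] <- chain[j]
    }
  }

  total_len <- route$required_scaffold_nt + max(excess, 0L)
  ord <- walk_cycle(nodes, start, total_len)
  letters_vec <- strsplit(scaffold$sequence, "")[[1L]][seq_len(total_len)]
  nodes$base[ord] <- letters_vec

  route$nodes <- nodes
  route$order <- ord
  route$scaffold <- scaffold
  route$start_node <- start
  route$excess_loop_nt <- max(excess, 0L)
  route$anchor_vertex <- anchor_vertex
  route
}

# lay the excess scaffold out as a compact helical coil anchored just
# outside the seam vertex (an explicit stand-in for the unstructured
# single-stranded loop; kept compact so large excesses stay inside the
# PDB coordinate bounds)
excess_loop_nodes <- function(route, nodes, vertex, n) {
  cst <- dx_constants()
  v_nm <- route$scaled$vertices_nm
  vp <- v_nm[vertex, ]
  nrm <- vp - colMeans(v_nm)
  if (sqrt(sum(nrm^2)) < 1e-9) nrm <- c(0, 0, 1)
  nrm <- nrm / sqrt(sum(nrm^2))
  t1 <- cross3(nrm, c(1, 0, 0))
  if (sqrt(sum(t1^2)) < 1e-6) t1 <- cross3(nrm, c(0, 1, 0))
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- cross3(nrm, t1)
  radius <- 15            # nm, coil radius
  pitch <- 2.5            # nm rise per turn
  a0 <- vp + 3 * nrm
  phi <- seq_len(n) * cst$ssdna_len_per_nt / radius
  pts <- t(vapply(phi, function(p)
    a0 + pitch * p / (2 * pi) * nrm +
      radius * (cos(p) * t1 + sin(p) * t2), numeric(3L)))
  base_id <- nrow(nodes)
  add <- data.table::data.table(
    id = base_id + seq_len(n), role = "scaffold", base = NA_character_,
    up = NA_integer_, down = NA_integer_, pair = NA_integer_,
    edge = NA_integer_, slot = NA_integer_, spos = NA_integer_,
    epos = NA_integer_, vertex = vertex,
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L], staple = NA_integer_)
  list(nodes = data.table::rbindlist(list(nodes, add)),
       ids = base_id + seq_len(n))
}
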