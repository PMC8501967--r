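#' Assemble a design configuration
#'
#' @param input fixture name (see [list_fixtures()]) or path to an ASCII
#'   PLY file.
#' @param min_edge_bp minimum edge length in base pairs (42-210).
#' @param edge_type edge motif; only `"dx"` (two-helix bundle) is
#'   implemented.  Six-helix-bundle edges are a documented extension
#'   point.
#' @param scaffold `"auto"` (length-based selection), `"m13"`,
#'   `"lambda"`, `"random"`, or a path to a plain-text/FASTA scaffold.
#' @param seed integer seed recorded in all outputs' provenance.
#' @param outdir output directory for [run_design()].
#' @param plate_layout add 96-well plate columns to the staple CSV.
#' @param multimodel emit one MODEL per strand in the PDB.
#' @param clash_cutoff clash report distance cutoff in Angstroms.
#' @param vertex_domain_bp vertex staple domain length (10 or 11).
#' @return A `dx_config` list.
#' @export
design_config <- function(input, min_edge_bp = 42L, edge_type = "dx",
                          scaffold = "auto", seed = 1L,
                          outdir = "dxwire_out", plate_layout = FALSE,
                          multimodel = FALSE, clash_cutoff = 2.0,
                          vertex_domain_bp = 11L) {
  cst <- dx_constants()
  if (!edge_type %in% "dx")
    dx_stop(sprintf(
      "edge_type '%s' not supported: only DX (two-helix bundle) edges are implemented",
      edge_type), "dx_config_error")
  if (min_edge_bp < cst$min_edge_bp_bound ||
      min_edge_bp > cst$max_edge_bp_bound)
    dx_stop(sprintf("min_edge_bp must lie in [%d, %d]",
                    cst$min_edge_bp_bound, cst$max_edge_bp_bound),
            "dx_bounds_error")
  structure(list(input = input, min_edge_bp = as.integer(min_edge_bp),
                 edge_type = edge_type, scaffold = scaffold,
                 seed = as.integer(seed), outdir = outdir,
                 plate_layout = isTRUE(plate_layout),
                 multimodel = isTRUE(multimodel),
                 clash_cutoff = clash_cutoff,
                 vertex_domain_bp = as.integer(vertex_domain_bp)),
            class = "dx_config")
}

config_hash <- function(config) {
  # hash the design-relevant parameters only (not the output location)
  c2 <- unclass(config)
  c2$outdir <- NULL
  txt <- paste(deparse(c2), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

dxwire_version <- function() {
  as.character(utils::packageVersion("dxwire"))
}

#' Run the full design pipeline
#'
#' Executes geometry reading/validation, base-pair scaling, design-graph
#' and spanning-tree construction, scaffold routing with vertex-gap
#' insertion, scaffold selection and sequence assignment, staple
#' generation, all-atom model building and clash detection, then writes
#' the output bundle: cylinder model (PLY), routing model (PLY line set),
#' pseudo-atomic model (PDB, one sphere per nucleotide), staple CSV,
#' caDNAno JSON, all-atom PDB, and a plain-text design summary.  Partial
#' outputs are removed on error.
#'
#' @param config a [design_config()].
#' @return Invisibly, the design bundle: list with all intermediate
#'   objects and `files` (named output paths).
#' @export
run_design <- function(config) {
  if (!inherits(config, "dx_config")) config <- do.call(design_config,
                                                        config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(cylinder = "cylinder_model.ply",
             routing = "routing_model.ply",
             pseudo = "pseudo_atomic.pdb",
             staples = "staples.csv",
             cadnano = "cadnano.json",
             pdb = "model.pdb",
             summary = "summary.txt")
  files <- stats::setNames(file.path(outdir, files), names(files))

  clean <- function() unlink(c(files, paste0(files["pdb"],
                                             ".strandmap.csv"),
                               paste0(files["cadnano"],
                                      ".crosssection.csv")))
  tryCatch({
    mesh <- if (file.exists(config$input)) read_ply(config$input)
    else generate_fixture(config$input, min_edge_bp = config$min_edge_bp,
                          seed = config$seed)
    scaled <- scale_mesh(mesh, config$min_edge_bp)
    graph <- build_graph(scaled)
    tree <- spanning_tree(graph)
    route <- route_scaffold(graph, tree, scaled)
    route <- insert_vertex_gaps(route, scaled)

    scaffold <- switch(
      config$scaffold,
      auto = select_scaffold(route$required_scaffold_nt,
                             seed = config$seed),
      m13 = select_scaffold_named("M13mp18", route$required_scaffold_nt),
      lambda = select_scaffold_named("Lambda",
                                     route$required_scaffold_nt),
      random = structure(list(
        name = "random",
        sequence = with_seed(config$seed, paste(
          sample(c("A", "C", "G", "T"), route$required_scaffold_nt,
                 replace = TRUE), collapse = "")),
        length = route$required_scaffold_nt, circular = TRUE),
        class = "dx_scaffold"),
      { # a path: user scaffold file
        if (!file.exists(config$scaffold))
          dx_stop(sprintf("scaffold file not found: %s", config$scaffold),
                  "dx_config_error")
        select_scaffold(route$required_scaffold_nt,
                        user_seq = read_fasta_seq(config$scaffold))
      })
    route <- assign_sequence(route, scaffold)
    staples <- generate_staples(route, tree, scaled,
                                vertex_domain_bp = config$vertex_domain_bp)
    atoms <- build_atoms(staples, route$frames)
    clashes <- detect_clashes(atoms, config$clash_cutoff)

    design <- list(config = config, config_hash = config_hash(config),
                   version = dxwire_version(),
                   mesh = mesh, scaled = scaled, graph = graph,
                   tree = tree, route = route, staples = staples,
                   atoms = atoms, clashes = clashes, files = files)

    prov <- c(sprintf("dxwire %s", design$version),
              sprintf("seed %d", config$seed),
              sprintf("config %s", design$config_hash))
    write_cylinder_model(scaled, route$frames, files["cylinder"],
                         comments = prov)
    write_routing_model(design, files["routing"], comments = prov)
    write_pseudo_atomic(design, files["pseudo"], provenance = prov)
    write_staple_csv(staples, files["staples"],
                     plate_layout = config$plate_layout)
    write_cadnano(staples, files["cadnano"],
                  name = sprintf("dxwire:%s", mesh$name))
    write_pdb(atoms, files["pdb"], multimodel = config$multimodel,
              provenance = prov)
    write_design_summary(design, files["summary"])
    invisible(design)
  }, dxwire_error = function(e) {
    clean()
    stop(e)
  }, error = function(e) {
    clean()
    stop(e)
  })
}

select_scaffold_named <- function(name, required_nt) {
  fname <- if (name == "M13mp18") "m13mp18_synthetic.fa" else
    "lambda_synthetic.fa"
  seq <- read_fasta_seq(scaffold_file(fname))
  if (nchar(seq) < required_nt)
    dx_stop(sprintf("scaffold %s (%d nt) shorter than required %d nt",
                    name, nchar(seq), required_nt),
            "dx_scaffold_length_error")
  structure(list(name = name, sequence = seq, length = nchar(seq),
                 circular = TRUE), class = "dx_scaffold")
}

#' Write the routing model (strand direction vectors) as PLY
#'
#' Approximates every strand by the polyline of its base-level node
#' positions: the scaffold as a closed cycle, each staple as an open
#' polyline, using the PLY `edge` element.
#'
#' @param design design bundle from [run_design()] internals (needs
#'   `staples`, `route`).
#' @param path output path.
#' @param comments provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_routing_model <- function(design, path, comments = character()) {
  nodes <- design$staples$nodes
  route <- design$route
  keep <- !is.na(nodes$x)
  ids <- nodes$id[keep]
  remap <- rep(NA_integer_, nrow(nodes))
  remap[ids] <- seq_along(ids) - 1L     # 0-based PLY indices
  segs <- list()
  ord <- route$order
  pos_ok <- !is.na(nodes$x[ord])
  ordp <- ord[pos_ok]
  segs[[1L]] <- cbind(remap[ordp], remap[c(ordp[-1L], ordp[1L])])
  stab <- design$staples$staples
  for (k in seq_len(nrow(stab))) {
    cur <- stab$first_node[k]
    pathv <- integer(0L)
    while (!is.na(cur)) {
      pathv <- c(pathv, cur)
      cur <- nodes$down[cur]
    }
    segs[[k + 1L]] <- cbind(remap[pathv[-length(pathv)]],
                            remap[pathv[-1L]])
  }
  ed <- do.call(rbind, segs)
  hdr <- c("ply", "format ascii 1.0",
           paste("comment", comments),
           sprintf("element vertex %d", length(ids)),
           "property float x", "property float y", "property float z",
           sprintf("element edge %d", nrow(ed)),
           "property int vertex1", "property int vertex2",
           "end_header")
  vtx <- sprintf("%.4f %.4f %.4f", nodes$x[ids], nodes$y[ids],
                 nodes$z[ids])
  writeLines(c(hdr, vtx, sprintf("%d %d", ed[, 1L], ed[, 2L])), path)
  invisible(path)
}

#' Write the pseudo-atomic model (one sphere per nucleotide)
#'
#' Emits a PDB with a single C1' pseudo-atom per nucleotide, chain per
#' strand — the light-weight model used for quick visual inspection of
#' helicity and strand identity.
#'
#' @param design design bundle (needs `atoms`).
#' @param path output path.
#' @param provenance REMARK lines.
#' @return `path`, invisibly.
#' @export
write_pseudo_atomic <- function(design, path, provenance = character()) {
  at <- design$atoms$atoms
  sub <- at[at$atom == "C1'", ]
  sub$serial <- seq_len(nrow(sub))
  pseudo <- list(atoms = sub, strands = design$atoms$strands)
  class(pseudo) <- "dx_atoms"
  write_pdb(pseudo, path, provenance = provenance)
}
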