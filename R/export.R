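#' Write the cylinder model of a design
#'
#' Renders each duplex axis as a cylinder of 2 nm diameter (the width of a
#' DNA double helix) and length `edge_bp * 0.332` nm, as an ASCII PLY mesh
#' (12-sided prisms with end caps).  Per-cylinder metadata (edge, helix
#' slot, diameter, length) is carried in PLY comment lines.
#'
#' @param scaled a [scale_mesh()] result.
#' @param frames the matching [place_helices()] frames.
#' @param path output PLY path.
#' @param sides prism facet count (default 12).
#' @param comments extra provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_cylinder_model <- function(scaled, frames, path, sides = 12L,
                                 comments = character()) {
  cst <- dx_constants()
  r <- cst$duplex_diameter / 2
  verts <- list()
  faces <- list()
  meta <- character()
  off <- 0L
  for (fr in frames$frames) {
    len <- fr$bp * cst$rise_per_bp
    a <- fr$origin - cst$rise_per_bp / 2 * fr$dir
    b <- a + len * fr$dir
    perp <- fr$ref
    ring <- vapply(seq_len(sides), function(k) {
      rotate_about(perp, fr$dir, 2 * pi * (k - 1) / sides) * r
    }, numeric(3L))
    va <- t(ring) + matrix(a, sides, 3L, byrow = TRUE)
    vb <- t(ring) + matrix(b, sides, 3L, byrow = TRUE)
    verts[[length(verts) + 1L]] <- rbind(va, vb)
    side_faces <- lapply(seq_len(sides), function(k) {
      k2 <- k %% sides + 1L
      off + c(k, k2, sides + k2, sides + k)
    })
    caps <- list(off + seq_len(sides), off + sides + rev(seq_len(sides)))
    faces <- c(faces, side_faces, caps)
    meta <- c(meta, sprintf(
      "cylinder edge %d slot %d diameter_nm %.1f length_nm %.2f",
      fr$edge, fr$slot, cst$duplex_diameter, len))
    off <- off + 2L * sides
  }
  write_ply(do.call(rbind, verts), faces, path,
            comments = c(comments, meta))
  invisible(path)
}

#' Write the staple sequences as CSV
#'
#' Columns: staple_id, class, edge_or_vertex, length_nt, sequence_5to3,
#' color, and (with `plate_layout`) plate and well assignments in
#' row-major A1..H12 order, 96 staples per plate.
#'
#' @param staples a [generate_staples()] result.
#' @param path output CSV path.
#' @param plate_layout add 96-well plate/well columns.
#' @return `path`, invisibly.
#' @export
write_staple_csv <- function(staples, path, plate_layout = FALSE) {
  tab <- as.data.frame(staples$staples[, c(
    "staple_id", "class", "edge_or_vertex", "length_nt",
    "sequence_5to3", "color")])
  if (plate_layout) {
    i <- seq_len(nrow(tab)) - 1L
    tab$plate <- i %/% 96L + 1L
    w <- i %% 96L
    tab$well <- paste0(LETTERS[w %/% 12L + 1L], w %% 12L + 1L)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the routing summary of a design
#'
#' Human-readable plain-text report: geometry, scaffold requirement and
#' selection, staple statistics, clash counts, and provenance (tool
#' version, seed, configuration hash).
#'
#' @param design a completed design bundle (see [run_design()]).
#' @param path output text path.
#' @return `path`, invisibly.
#' @export
write_design_summary <- function(design, path) {
  rt <- design$route
  sc <- design$scaled
  stats <- staple_statistics(design$staples)
  cl <- design$clashes
  lines <- c(
    "# dxwire design summary",
    sprintf("tool_version: %s", design$version),
    sprintf("seed: %s", design$config$seed),
    sprintf("config_hash: %s", design$config_hash),
    sprintf("geometry: %s", sc$mesh$name),
    sprintf("vertices: %d", nrow(sc$mesh$vertices)),
    sprintf("edges: %d", nrow(sc$mesh$edges)),
    sprintf("faces: %d", length(sc$mesh$faces)),
    sprintf("min_edge_bp: %d", sc$min_edge_bp),
    sprintf("edge_bp: %s", paste(sc$edge_bp, collapse = " ")),
    sprintf("edge_nm: %s", paste(sprintf("%.2f", sc$edge_nm),
                                 collapse = " ")),
    sprintf("total_paired_nt: %d", rt$total_paired_nt),
    sprintf("total_unpaired_nt: %d", rt$total_unpaired_nt),
    sprintf("required_scaffold_nt: %d", rt$required_scaffold_nt),
    sprintf("scaffold_name: %s", rt$scaffold$name),
    sprintf("scaffold_length_nt: %d", rt$scaffold$length),
    sprintf("excess_loop_nt: %d", rt$excess_loop_nt),
    sprintf("scaffold_crossovers: %d", length(rt$crossovers)),
    sprintf("staple_count: %d", stats$n_staples),
    sprintf("staple_nt: %d", stats$total_nt),
    sprintf("staple_length_range: %d %d", stats$length_range[1L],
            stats$length_range[2L]),
    sprintf("vertex_staples: %d", stats$n_vertex),
    sprintf("edge_staples: %d", stats$n_edge),
    sprintf("atoms: %d", nrow(design$atoms$atoms)),
    sprintf("strands: %d", nrow(design$atoms$strands)),
    sprintf("clash_cutoff_A: %.1f", cl$cutoff),
    sprintf("clash_count: %d", cl$n_clashes))
  if (nrow(cl$by_vertex) > 0L)
    lines <- c(lines, sprintf("clashes_vertex_%s: %s",
                              cl$by_vertex$vertex, cl$by_vertex$Freq))
  writeLines(lines, path)
  invisible(path)
}
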