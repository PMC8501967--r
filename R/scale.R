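#' Quantize a mesh to base-pair edge lengths
#'
#' The minimum edge length `min_edge_bp` is assigned to the shortest mesh
#' edge, which then scales all other edges proportionally; every edge is
#' rounded to the nearest integer number of base pairs (ties to even, the
#' R default).  Physical lengths follow as `edge_bp * 0.332` nm.  Mesh
#' units are treated as purely relative: the absolute size of the design
#' comes solely from `min_edge_bp`.
#'
#' @param mesh a [dx_mesh()].
#' @param min_edge_bp integer in \[42, 210\]: base pairs on the shortest
#'   edge (two full helical turns up to the supported maximum).
#' @return An object of class `dx_scaled`: list with the `mesh`, integer
#'   `edge_bp` per edge (ordered as `mesh$edges`), `edge_nm`,
#'   `scale_factor` (nm per mesh unit) and `vertices_nm` (scaled vertex
#'   coordinates).
#' @export
#' @examples
#' sc <- scale_mesh(generate_fixture("tetrahedron"), 42)
#' unique(sc$edge_bp)
#' round(unique(sc$edge_nm), 2)
scale_mesh <- function(mesh, min_edge_bp) {
  cst <- dx_constants()
  if (!inherits(mesh, "dx_mesh"))
    dx_stop("mesh must be a dx_mesh", "dx_validation_error")
  min_edge_bp <- as.integer(min_edge_bp)
  if (is.na(min_edge_bp) || min_edge_bp < cst$min_edge_bp_bound ||
      min_edge_bp > cst$max_edge_bp_bound)
    dx_stop(sprintf("min_edge_bp must lie in [%d, %d], got %s",
                    cst$min_edge_bp_bound, cst$max_edge_bp_bound,
                    min_edge_bp), "dx_bounds_error")

  len <- edge_lengths(mesh)
  lmin <- min(len)
  edge_bp <- as.integer(round(len / lmin * min_edge_bp))
  stopifnot(min(edge_bp) == min_edge_bp, all(edge_bp >= 1L))
  scale_factor <- min_edge_bp * cst$rise_per_bp / lmin
  structure(list(
    mesh = mesh,
    edge_bp = edge_bp,
    edge_nm = edge_bp * cst$rise_per_bp,
    scale_factor = scale_factor,
    vertices_nm = mesh$vertices * scale_factor,
    min_edge_bp = min_edge_bp
  ), class = "dx_scaled")
}

edge_lengths <- function(mesh) {
  sqrt(rowSums((mesh$vertices[mesh$edges[, 1L], , drop = FALSE] -
                mesh$vertices[mesh$edges[, 2L], , drop = FALSE])^2))
}

#' @export
print.dx_scaled <- function(x, ...) {
  cat(sprintf(
    "dx_scaled '%s': %d edges, %d-%d bp (%.2f-%.2f nm), %.4f nm/unit\n",
    x$mesh$name, length(x$edge_bp), min(x$edge_bp), max(x$edge_bp),
    min(x$edge_nm), max(x$edge_nm), x$scale_factor))
  invisible(x)
}
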