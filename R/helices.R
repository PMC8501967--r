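#' Place the two duplex axes of every DX edge
#'
#' Each wireframe edge is realized as two antiparallel B-form duplexes.
#' The two axes run parallel to the edge vector and are offset
#' symmetrically by half the inter-helix spacing along the local
#' face-bisector normal, so that each duplex lies on the side of one of
#' the edge's two incident faces and the inter-axis distance equals
#' `interhelix_spacing` exactly.  The duplex occupies `edge_bp * 0.332` nm
#' centred on the edge midpoint.  Frame direction is the 5'->3' travel
#' direction of the scaffold strand on that duplex (fixed by the face
#' winding); the twist reference axis of each helix points toward its
#' partner helix.
#'
#' @param scaled a [scale_mesh()] result.
#' @return Object of class `dx_frames`: list of per-duplex frames, each
#'   with `edge`, `slot` (1 = first incident face, 2 = second), `face`,
#'   `bp`, `polarity` (+1 if the scaffold runs from the lower to the
#'   higher vertex index), `origin` (centre of the first base pair along
#'   scaffold travel, nm), `dir` (unit), `ref` (unit twist reference),
#'   `twist_offset` (degrees).
#' @export
place_helices <- function(scaled) {
  mesh <- scaled$mesh
  cst <- dx_constants()
  v_nm <- scaled$vertices_nm
  edges <- mesh$edges
  ne <- nrow(edges)

  centroids <- t(vapply(mesh$faces, function(f)
    colMeans(v_nm[f, , drop = FALSE]), numeric(3L)))

  ekey <- paste(edges[, 1L], edges[, 2L])
  # directed traversal of each edge by each face
  trav <- vector("list", ne)    # per edge: face -> +1 (v1->v2) or -1
  for (fi in seq_along(mesh$faces)) {
    f <- mesh$faces[[fi]]
    a <- f; b <- c(f[-1L], f[1L])
    ids <- match(paste(pmin(a, b), pmax(a, b)), ekey)
    for (j in seq_along(ids)) {
      e <- ids[j]
      trav[[e]] <- c(trav[[e]],
                     stats::setNames(if (a[j] < b[j]) 1L else -1L, fi))
    }
  }

  frames <- list()
  for (e in seq_len(ne)) {
    n <- scaled$edge_bp[e]
    if (n < 1L) dx_stop(sprintf("edge %d degenerate", e), "dx_geometry_error")
    p1 <- v_nm[edges[e, 1L], ]
    p2 <- v_nm[edges[e, 2L], ]
    ev <- p2 - p1
    elen <- sqrt(sum(ev^2))
    if (elen < 1e-9)
      dx_stop(sprintf("edge %d has zero length", e), "dx_geometry_error")
    d12 <- ev / elen
    mid <- (p1 + p2) / 2
    fids <- as.integer(names(trav[[e]]))
    tvec <- lapply(fids, function(fi) {
      t0 <- centroids[fi, ] - mid
      t0 <- t0 - sum(t0 * d12) * d12       # in-plane, perpendicular to edge
      t0 / sqrt(sum(t0^2))
    })
    bis <- tvec[[1L]] - tvec[[2L]]
    bis <- bis / sqrt(sum(bis^2))          # points to the slot-1 face side
    half_len <- n * cst$rise_per_bp / 2
    for (slot in 1:2) {
      off <- (if (slot == 1L) 1 else -1) * cst$interhelix_spacing / 2 * bis
      pol <- trav[[e]][slot]
      dir <- if (pol > 0L) d12 else -d12
      start <- mid - half_len * dir + off  # vertex-side end, scaffold entry
      frames[[length(frames) + 1L]] <- list(
        edge = e, slot = slot, face = fids[slot], bp = n,
        polarity = as.integer(pol),
        origin = start + cst$rise_per_bp / 2 * dir,
        dir = dir,
        ref = -(if (slot == 1L) 1 else -1) * bis,  # toward partner helix
        twist_offset = 0
      )
    }
  }
  structure(list(frames = frames,
                 index = frame_index(frames)), class = "dx_frames")
}

frame_index <- function(frames) {
  key <- vapply(frames, function(f) paste(f$edge, f$slot), character(1L))
  stats::setNames(seq_along(frames), key)
}

get_frame <- function(frames, edge, slot) {
  frames$frames[[frames$index[[paste(edge, slot)]]]]
}

#' Rigid transform of base-pair `index` along a helix frame
#'
#' The base-pair centre advances by 0.332 nm per index along the helix
#' direction and the base-pair frame rotates by 360/10.5 degrees per index
#' about it (plus the per-helix twist offset).
#'
#' @param frame one frame from [place_helices()].
#' @param index 0-based base-pair index along the frame direction,
#'   `0 <= index < bp`.
#' @return List with `origin` (nm) and `rot` (3x3 matrix whose columns are
#'   the images of the base-pair frame x, y, z axes).
#' @export
base_frame <- function(frame, index) {
  if (index < 0L || index >= frame$bp)
    dx_stop(sprintf("base index %d out of range [0, %d)", index, frame$bp),
            "dx_bounds_error")
  cst <- dx_constants()
  ang <- (frame$twist_offset + index * 360 / cst$bp_per_turn) * pi / 180
  yhat <- rotate_about(frame$ref, frame$dir, ang)
  xhat <- cross3(yhat, frame$dir)
  list(origin = frame$origin + index * cst$rise_per_bp * frame$dir,
       rot = cbind(xhat, yhat, frame$dir),
       twist_deg = frame$twist_offset + index * 360 / cst$bp_per_turn)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

rotate_about <- function(v, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(theta) + cross3(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}
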