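#' Built-in target geometries
#'
#' Deterministic generators for the bundled polyhedral test geometries.
#' `asymmetric_octahedron` emulates an irregular design target: the six
#' vertices of a regular octahedron are perturbed with seeded uniform
#' noise of +/-15% of the edge length in each coordinate, giving twelve
#' distinct edge lengths and irregular vertex angles.  When `min_edge_bp`
#' is supplied the generator additionally guarantees that all scaled
#' base-pair edge lengths are pairwise distinct, re-drawing from a derived
#' seed on the (rare) collision.
#'
#' @param name one of [list_fixtures()]: `tetrahedron`, `cube`,
#'   `octahedron`, `icosahedron`, `pentagonal_bipyramid`,
#'   `asymmetric_octahedron`.
#' @param min_edge_bp optional minimum edge length in bp; only used by
#'   `asymmetric_octahedron` to enforce distinct quantized edge lengths.
#' @param seed integer seed for the perturbation (default 1).
#' @return A validated [dx_mesh()].
#' @export
#' @examples
#' generate_fixture("octahedron")
generate_fixture <- function(name, min_edge_bp = NULL, seed = 1L) {
  cat_fun <- fixture_catalogue()[[name]]
  if (is.null(cat_fun))
    dx_stop(sprintf("unknown fixture '%s'; see list_fixtures()", name),
            "dx_catalogue_error")
  cat_fun(min_edge_bp = min_edge_bp, seed = seed)
}

#' List the bundled fixture geometries
#'
#' @return Data frame of fixture names with vertex/edge/face counts,
#'   sorted by name.
#' @export
list_fixtures <- function() {
  nms <- sort(names(fixture_catalogue()))
  stats <- lapply(nms, function(n) {
    m <- generate_fixture(n, seed = 1L)
    data.frame(name = n, vertices = nrow(m$vertices),
               edges = nrow(m$edges), faces = length(m$faces))
  })
  do.call(rbind, stats)
}

fixture_catalogue <- function() {
  list(
    tetrahedron = function(...) {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      dx_mesh(v, triangles_by_min_distance(v), name = "tetrahedron")
    },
    cube = function(...) {
      v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
      f <- list(c(1L, 2L, 4L, 3L), c(5L, 7L, 8L, 6L),
                c(1L, 3L, 7L, 5L), c(2L, 6L, 8L, 4L),
                c(1L, 5L, 6L, 2L), c(3L, 4L, 8L, 7L))
      dx_mesh(v, f, name = "cube")
    },
    octahedron = function(...) {
      dx_mesh(octa_vertices(), triangles_by_min_distance(octa_vertices()),
              name = "octahedron")
    },
    icosahedron = function(...) {
      p <- (1 + sqrt(5)) / 2
      v <- rbind(c(0, 1, p), c(0, 1, -p), c(0, -1, p), c(0, -1, -p),
                 c(1, p, 0), c(1, -p, 0), c(-1, p, 0), c(-1, -p, 0),
                 c(p, 0, 1), c(-p, 0, 1), c(p, 0, -1), c(-p, 0, -1))
      dx_mesh(v, triangles_by_min_distance(v), name = "icosahedron")
    },
    pentagonal_bipyramid = function(...) {
      th <- 2 * pi * (0:4) / 5
      v <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1), c(0, 0, -1))
      f <- c(lapply(0:4, function(i) c(i + 1L, (i + 1L) %% 5L + 1L, 6L)),
             lapply(0:4, function(i) c((i + 1L) %% 5L + 1L, i + 1L, 7L)))
      dx_mesh(v, f, name = "pentagonal_bipyramid")
    },
    asymmetric_octahedron = function(min_edge_bp = NULL, seed = 1L, ...) {
      asymmetric_octahedron(min_edge_bp, seed)
    }
  )
}

octa_vertices <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# faces of a regular deltahedron: all vertex triples that are pairwise at
# the minimum inter-vertex distance; winding fixed by the repair pass
triangles_by_min_distance <- function(v, tol = 1e-6) {
  d <- as.matrix(dist(v))
  diag(d) <- Inf
  emin <- min(d)
  adj <- d < emin * (1 + tol)
  n <- nrow(v)
  out <- list()
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n)
    if (adj[i, j] && adj[j, k] && adj[i, k])
      out[[length(out) + 1L]] <- c(i, j, k)
  out
}

asymmetric_octahedron <- function(min_edge_bp = NULL, seed = 1L) {
  base <- octa_vertices()
  edge_len <- sqrt(2)
  for (attempt in 0:31) {
    v <- with_seed(seed + 1000L * attempt, {
      base + matrix(runif(18L, -0.15, 0.15) * edge_len, ncol = 3L)
    })
    mesh <- dx_mesh(v, triangles_by_min_distance(base),
                    name = "asymmetric_octahedron")
    if (is.null(min_edge_bp)) return(mesh)
    sc <- scale_mesh(mesh, min_edge_bp)
    if (!anyDuplicated(sc$edge_bp)) return(mesh)
  }
  dx_stop("could not realize distinct edge lengths", "dx_catalogue_error")
}
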