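#' Read a polygonal mesh from an ASCII PLY file
#'
#' Parses the `vertex` element (properties x, y, z) and the `face` element
#' (a `vertex_indices`/`vertex_index` list property) of an ASCII PLY file
#' and returns a validated [dx_mesh()].  Binary PLY files are rejected:
#' converters to ASCII PLY are widely available.
#'
#' @param path path to an ASCII PLY file.
#' @return A validated `dx_mesh`.
#' @export
read_ply <- function(path) {
  if (!file.exists(path))
    dx_stop(sprintf("file not found: %s", path), "dx_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) < 4L || lines[1L] != "ply")
    dx_stop("not a PLY file (missing 'ply' magic)", "dx_parse_error")
  end_hdr <- match("end_header", lines)
  if (is.na(end_hdr))
    dx_stop("malformed PLY header: no end_header", "dx_parse_error")
  hdr <- lines[2:(end_hdr - 1L)]
  fmt <- grep("^format ", hdr, value = TRUE)
  if (length(fmt) != 1L)
    dx_stop("malformed PLY header: missing format line", "dx_parse_error")
  if (!grepl("^format\\s+ascii", fmt))
    dx_stop("binary PLY is not supported; convert to ASCII PLY",
            "dx_parse_error")

  # parse element declarations in order
  elems <- list()
  cur <- NULL
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elems[[cur]] <- list(count = as.integer(tok[3L]), props = character())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[length(tok)])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    dx_stop("PLY must declare vertex and face elements", "dx_parse_error")

  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(body)]
  need <- sum(vapply(elems, function(e) e$count, integer(1L)))
  if (length(body) < need)
    dx_stop("PLY body truncated", "dx_parse_error")

  at <- 1L
  vertices <- NULL
  faces <- NULL
  for (nm in names(elems)) {
    n <- elems[[nm]]$count
    chunk <- body[at:(at + n - 1L)]
    at <- at + n
    if (nm == "vertex") {
      props <- elems[[nm]]$props
      ix <- match(c("x", "y", "z"), props)
      if (anyNA(ix))
        dx_stop("vertex element lacks x/y/z properties", "dx_parse_error")
      vals <- lapply(strsplit(chunk, "\\s+"), as.numeric)
      if (any(vapply(vals, length, integer(1L)) < max(ix)))
        dx_stop("malformed vertex row", "dx_parse_error")
      vertices <- t(vapply(vals, function(v) v[ix], numeric(3L)))
    } else if (nm == "face") {
      faces <- lapply(strsplit(chunk, "\\s+"), function(tok) {
        v <- suppressWarnings(as.integer(tok))
        if (anyNA(v)) dx_stop("malformed face row", "dx_parse_error")
        k <- v[1L]
        if (length(v) != k + 1L)
          dx_stop("face vertex count does not match its list length",
                  "dx_parse_error")
        v[-1L] + 1L   # PLY is 0-based
      })
    }
  }
  dx_mesh(vertices, faces, name = basename(path))
}

#' Write a mesh as an ASCII PLY file
#'
#' Inverse of [read_ply()]; used for the cylinder model export and for
#' round-trip tests.  Comment lines can carry provenance.
#'
#' @param vertices numeric n x 3 matrix.
#' @param faces list of 1-based integer index vectors.
#' @param path output file path.
#' @param comments character vector written as `comment` header lines.
#' @return `path`, invisibly.
#' @export
write_ply <- function(vertices, faces, path, comments = character()) {
  hdr <- c("ply", "format ascii 1.0",
           paste("comment", comments),
           sprintf("element vertex %d", nrow(vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", length(faces)),
           "property list uchar int vertex_indices",
           "end_header")
  vtx <- apply(vertices, 1L, function(r)
    paste(formatC(r, format = "g", digits = 8), collapse = " "))
  fc <- vapply(faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), character(1L))
  writeLines(c(hdr, vtx, fc), path)
  invisible(path)
}
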