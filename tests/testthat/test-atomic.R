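test_that("helix placement satisfies the DX edge geometry", {
  cst <- dx_constants()
  sc <- scale_mesh(generate_fixture("tetrahedron"), 42L)
  fr <- place_helices(sc)
  by_edge <- split(fr$frames,
                   vapply(fr$frames, function(f) f$edge, integer(1L)))
  for (pair in by_edge) {
    a <- pair[[1L]]; b <- pair[[2L]]
    # antiparallel axes
    expect_equal(sum(a$dir * b$dir), -1, tolerance = 1e-9)
    # inter-axis distance = interhelix spacing (axes are parallel lines)
    w <- a$origin - b$origin
    w_perp <- w - sum(w * a$dir) * a$dir
    expect_equal(sqrt(sum(w_perp^2)), cst$interhelix_spacing,
                 tolerance = 1e-9)
    # 42-bp axis length = 13.94 nm (2 d.p.)
    expect_equal(round(a$bp * cst$rise_per_bp, 2), 13.94)
  }
  # degenerate edge rejected
  degen <- structure(list(mesh = generate_fixture("tetrahedron"),
                          edge_bp = rep(0L, 6L)), class = "dx_scaled")
  degen$vertices_nm <- degen$mesh$vertices
  expect_error(place_helices(degen), class = "dx_geometry_error")
})

test_that("helix placement is equivariant under reflection", {
  m <- generate_fixture("pentagonal_bipyramid")
  sc <- scale_mesh(m, 42L)
  fr <- place_helices(sc)
  mm <- dx_mesh(m$vertices %*% diag(c(-1, 1, 1)), m$faces)
  frm <- place_helices(scale_mesh(mm, 42L))
  # reflection reverses face windings, hence scaffold polarity (DNA
  # chirality): compare the unordered helix axis segments per edge
  key <- function(f, reflect) {
    cst <- dx_constants()
    a <- f$origin
    b <- f$origin + (f$bp - 1L) * cst$rise_per_bp * f$dir
    if (reflect) { a <- a * c(-1, 1, 1); b <- b * c(-1, 1, 1) }
    ends <- rbind(round(a, 6), round(b, 6))
    ends <- ends[order(ends[, 1L], ends[, 2L], ends[, 3L]), ]
    paste(f$edge, paste(t(ends), collapse = ","))
  }
  expect_setequal(vapply(fr$frames, key, character(1L), reflect = TRUE),
                  vapply(frm$frames, key, character(1L), reflect = FALSE))
})

test_that("base_frame advances rise and twist correctly", {
  sc <- scale_mesh(generate_fixture("tetrahedron"), 42L)
  fr <- place_helices(sc)$frames[[1L]]
  b0 <- base_frame(fr, 0L)
  expect_equal(b0$origin, fr$origin)
  expect_equal(b0$rot[, 2L], fr$ref, tolerance = 1e-12)  # identity twist
  b1 <- base_frame(fr, 1L)
  expect_equal(b1$twist_deg, 360 / 10.5)
  ang <- acos(max(-1, min(1, sum(b1$rot[, 2L] * b0$rot[, 2L]))))
  expect_equal(ang * 180 / pi, 34.2857142857, tolerance = 1e-6)
  # 21 bp = two full turns
  b21 <- base_frame(fr, 21L)
  expect_equal(b21$rot, b0$rot, tolerance = 1e-9)
  expect_equal(sqrt(sum((b21$origin - b0$origin)^2)), 21 * 0.332,
               tolerance = 1e-9)
  expect_error(base_frame(fr, -1L), class = "dx_bounds_error")
  expect_error(base_frame(fr, fr$bp), class = "dx_bounds_error")
})

test_that("cubic Bezier interpolation matches the Bernstein oracle", {
  # collinear handles -> straight, equally spaced anchors
  span <- list(p0 = c(0, 0, 0), p1 = c(1, 0, 0), p2 = c(2, 0, 0),
               p3 = c(3, 0, 0), n = 5L)
  pts <- interpolate_ssdna(span)
  expect_equal(pts[, 1L], 3 * (1:5) / 6, tolerance = 1e-12)
  expect_equal(pts[, 2L], rep(0, 5L))

  # symmetric elbow: midpoint against direct polynomial evaluation
  p0 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  sp <- dxwire:::bezier_span(p0, p3, t_up = c(0, 1, 0),
                             t_dn = c(0, -1, 0), n = 1L)
  mid <- interpolate_ssdna(sp)[1L, ]
  bern <- function(t, P) (1 - t)^3 * P[[1L]] + 3 * (1 - t)^2 * t * P[[2L]] +
    3 * (1 - t) * t^2 * P[[3L]] + t^3 * P[[4L]]
  expect_equal(mid, bern(0.5, list(sp$p0, sp$p1, sp$p2, sp$p3)),
               tolerance = 1e-12)

  # endpoint identity of the Bernstein form used
  expect_equal(bern(0, list(sp$p0, sp$p1, sp$p2, sp$p3)), p0)
  expect_equal(bern(1, list(sp$p0, sp$p1, sp$p2, sp$p3)), p3)

  # anchors monotone in parameter and inside the control-point hull
  sp2 <- dxwire:::bezier_span(c(0, 0, 0), c(10, 0, 0), c(1, 0, 0),
                              c(1, 0, 0), n = 7L)
  pts2 <- interpolate_ssdna(sp2)
  expect_true(all(diff(pts2[, 1L]) > 0))
  hull_lo <- pmin(sp2$p0, sp2$p1, sp2$p2, sp2$p3)
  hull_hi <- pmax(sp2$p0, sp2$p1, sp2$p2, sp2$p3)
  for (k in 1:3)
    expect_true(all(pts2[, k] >= hull_lo[k] - 1e-12 &
                      pts2[, k] <= hull_hi[k] + 1e-12))

  # degenerate coincident endpoints are legal
  spd <- list(p0 = c(1, 1, 1), p1 = c(1, 1, 1), p2 = c(1, 1, 1),
              p3 = c(1, 1, 1), n = 3L)
  expect_true(all(interpolate_ssdna(spd) == 1))
  expect_error(interpolate_ssdna(list(p0 = c(0, 0, 0), p1 = c(0, 0, 0),
                                      p2 = c(0, 0, 0), p3 = c(0, 0, 0),
                                      n = 0L)),
               class = "dx_bounds_error")
})

test_that("atom building conserves counts and template geometry", {
  d <- small_design("tetrahedron", 42L)
  aa <- small_atoms("tetrahedron", 42L)
  # strand count = scaffold + staples
  expect_equal(nrow(aa$strands), 1L + nrow(d$staples$staples))
  # atom count = sum of per-residue manifest counts
  man <- template_manifest()
  resn <- c(A = "DA", C = "DC", G = "DG", T = "DT")
  bases <- d$staples$nodes$base
  expect_equal(nrow(aa$atoms), sum(man[resn[bases]]))
  # per-residue heavy-atom counts match the manifest exactly
  cnt <- table(aa$atoms$residue) / table(factor(resn[bases],
                                                levels = names(man)))
  expect_equal(as.numeric(cnt), as.numeric(man[names(cnt)]))
  # paired C1'-C1' distances within 10.85 +/- 1.5 A on duplex regions
  c1 <- aa$atoms[aa$atoms$atom == "C1'", ]
  nd <- aa$nodes
  pr <- nd[!is.na(nd$pair) & nd$role == "scaffold", ]
  i1 <- match(pr$id, c1$node); i2 <- match(pr$pair, c1$node)
  dd <- sqrt((c1$x[i1] - c1$x[i2])^2 + (c1$y[i1] - c1$y[i2])^2 +
               (c1$z[i1] - c1$z[i2])^2)
  expect_true(all(abs(dd - 10.85) <= 1.5))
  expect_true(all(is.finite(as.matrix(aa$atoms[, c("x", "y", "z")]))))
})

test_that("a placed A:T pair round-trips through its transform", {
  tpl <- load_templates()
  sc <- scale_mesh(generate_fixture("tetrahedron"), 42L)
  fr <- place_helices(sc)$frames[[3L]]
  bf <- base_frame(fr, 7L)
  td <- rbind(tpl$A$scaffold, tpl$A$partner)
  xyz <- as.matrix(td[, c("x", "y", "z")]) / 10
  world <- xyz %*% t(bf$rot) +
    matrix(bf$origin, nrow(td), 3L, byrow = TRUE)
  back <- (world - matrix(bf$origin, nrow(td), 3L, byrow = TRUE)) %*%
    bf$rot
  expect_equal(back, xyz, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("atom building is equivariant under rigid rotation", {
  d1 <- small_design("tetrahedron", 42L)
  a1 <- small_atoms("tetrahedron", 42L)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- dx_mesh(generate_fixture("tetrahedron")$vertices %*% t(R),
                generate_fixture("tetrahedron")$faces)
  sc2 <- scale_mesh(m2, 42L)
  g2 <- build_graph(sc2)
  t2 <- spanning_tree(g2)
  r2 <- insert_vertex_gaps(route_scaffold(g2, t2, sc2), sc2)
  r2 <- assign_sequence(r2, select_scaffold(
    r2$required_scaffold_nt,
    user_seq = exact_scaffold(r2$required_scaffold_nt)))
  a2 <- build_atoms(generate_staples(r2, t2, sc2), r2$frames)
  x1 <- as.matrix(a1$atoms[, c("x", "y", "z")])
  x2 <- as.matrix(a2$atoms[, c("x", "y", "z")])
  rmsd <- sqrt(mean(rowSums((x1 %*% t(R) - x2)^2)))
  expect_lt(rmsd, 1e-6)
})

test_that("clash detection reports symmetric pairs above the template floor", {
  # synthetic two-atom structure 1.0 A apart in different nucleotides
  toy <- list(
    atoms = data.table::data.table(
      serial = 1:2, strand = 1L, strand_role = "staple", resseq = 1:2,
      residue = "DA", atom = c("N1", "N3"), element = "N",
      x = c(0, 1), y = c(0, 0), z = c(0, 0), node = 1:2),
    nodes = data.table::data.table(
      id = 1:2, role = "scaffold", down = c(NA_integer_, NA_integer_),
      edge = NA_integer_, slot = NA_integer_, epos = NA_integer_),
    scaled = list(vertices_nm = matrix(0, 1, 3)))
  class(toy) <- "dx_atoms"
  rep1 <- detect_clashes(toy, 2.0)
  expect_equal(rep1$n_clashes, 1L)       # listed exactly once
  expect_error(detect_clashes(toy, -1), class = "dx_bounds_error")

  # duplex-only toy straight from the templates: clash-free at 2.0 A
  tpl <- load_templates()
  seqs <- c("A", "C", "G", "T", "A", "G", "C", "T", "T", "G")
  rows <- list()
  nodes <- list()
  twist <- 2 * pi / 10.5
  nid <- 0L
  for (i in seq_along(seqs)) {
    td <- rbind(cbind(tpl[[seqs[i]]]$scaffold, who = "s"),
                cbind(tpl[[seqs[i]]]$partner, who = "p"))
    R <- rbind(c(cos((i - 1) * twist), -sin((i - 1) * twist), 0),
               c(sin((i - 1) * twist), cos((i - 1) * twist), 0),
               c(0, 0, 1))
    w <- as.matrix(td[, c("x", "y", "z")]) %*% t(R)
    w[, 3L] <- w[, 3L] + (i - 1) * 3.32
    for (who in c("s", "p")) {
      nid <- nid + 1L
      sel <- td$who == who
      rows[[nid]] <- data.table::data.table(
        serial = 0L, strand = if (who == "s") 1L else 2L,
        strand_role = "x", resseq = i, residue = td$residue[sel],
        atom = td$atom[sel], element = td$element[sel],
        x = w[sel, 1L], y = w[sel, 2L], z = w[sel, 3L], node = nid)
    }
  }
  at <- data.table::rbindlist(rows)
  at$serial <- seq_len(nrow(at))
  # scaffold nodes odd ids ascending; partner even ids descending
  n <- length(seqs)
  nodes <- data.table::data.table(
    id = seq_len(2L * n), role = "x",
    down = NA_integer_, edge = 1L,
    slot = rep(1:2, n), epos = rep(seq_len(n), each = 2L))
  nodes$down[nodes$slot == 1L] <-
    c(nodes$id[nodes$slot == 1L][-1L], NA_integer_)
  ids2 <- rev(nodes$id[nodes$slot == 2L])
  nodes$down[ids2] <- c(ids2[-1L], NA_integer_)
  toy2 <- list(atoms = at, nodes = nodes,
               scaled = list(vertices_nm = matrix(0, 1, 3)))
  class(toy2) <- "dx_atoms"
  # brute-force oracle confirms the cell-list result
  rep2 <- detect_clashes(toy2, 2.0)
  expect_equal(rep2$n_clashes, 0L)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  same_node <- outer(at$node, at$node, "==")
  dn <- nodes$down
  bb1 <- at$atom %in% c("C3'", "O3'", "C2'")
  bb2 <- at$atom %in% c("P", "O5'", "OP1", "OP2")
  link <- outer(seq_len(nrow(at)), seq_len(nrow(at)), function(i, j) {
    (!is.na(dn[at$node[i]]) & dn[at$node[i]] == at$node[j] &
       bb1[i] & bb2[j]) |
      (!is.na(dn[at$node[j]]) & dn[at$node[j]] == at$node[i] &
         bb1[j] & bb2[i])
  })
  viol <- dmat < 2.0 & !same_node & !link
  expect_equal(sum(viol), 0L)
})
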