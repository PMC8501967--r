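test_that("design graph carries degrees and cyclic edge orders", {
  g <- build_graph(scale_mesh(generate_fixture("tetrahedron"), 42L))
  expect_equal(g$n_nodes, 4L)
  expect_equal(nrow(g$arcs), 6L)
  deg <- table(c(g$arcs$v1, g$arcs$v2))
  expect_true(all(deg == 3L))

  go <- build_graph(scale_mesh(generate_fixture("octahedron"), 42L))
  expect_true(all(lengths(go$cyclic) == 4L))
  # cyclic order contains each incident edge exactly once
  for (v in seq_len(go$n_nodes)) {
    inc <- which(go$arcs$v1 == v | go$arcs$v2 == v)
    expect_setequal(go$cyclic[[v]], inc)
  }
})

test_that("spanning tree is deterministic and matches the K4 oracle", {
  g <- build_graph(scale_mesh(generate_fixture("tetrahedron"), 42L))
  tr <- spanning_tree(g)
  expect_equal(length(tr$arcs), 3L)
  expect_identical(spanning_tree(g)$arcs, tr$arcs)

  # brute-force oracle: enumerate all 3-subsets of the 6 arcs of K4 and
  # keep the acyclic spanning ones (Cayley: 4^2 = 16)
  arcs <- g$arcs
  spanning <- list()
  for (s in utils::combn(6L, 3L, simplify = FALSE)) {
    parent <- 1:4
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in s) {
      ra <- find(arcs$v1[e]); rb <- find(arcs$v2[e])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) spanning[[length(spanning) + 1L]] <- s
  }
  expect_equal(length(spanning), 16L)
  expect_true(any(vapply(spanning, function(s)
    identical(sort(s), tr$arcs), logical(1L))))
})

test_that("scaffold routing closes one loop with the right invariants", {
  for (nm in c("tetrahedron", "cube", "octahedron",
               "pentagonal_bipyramid")) {
    d <- small_design(nm, 42L)
    rt <- d$route
    arcs <- d$graph$arcs
    expect_equal(rt$total_paired_nt, 2L * sum(arcs$bp))
    # crossover count = cyclomatic number E - V + 1
    expect_equal(length(rt$crossovers),
                 nrow(arcs) - d$graph$n_nodes + 1L)
    # single-loop property from an arbitrary interior node
    nodes <- rt$nodes
    startv <- rt$nodes$id[200L %% nrow(nodes) + 1L]
    cur <- startv
    for (i in seq_len(rt$required_scaffold_nt + rt$excess_loop_nt)) {
      cur <- nodes$down[cur]
    }
    expect_equal(cur, startv)
    # conservation: no scaffold base paired twice
    pr <- nodes$pair[nodes$role == "scaffold"]
    pr <- pr[!is.na(pr)]
    expect_equal(anyDuplicated(pr), 0L)
  }
})

test_that("tetrahedron at 42 bp pairs 504 scaffold nucleotides", {
  d <- small_design("tetrahedron", 42L)
  expect_equal(d$route$total_paired_nt, 504L)
  nodes <- d$staples$nodes
  expect_equal(sum(!is.na(nodes$pair) & nodes$role == "scaffold"), 504L)
})

test_that("asymmetric octahedra route a single loop for several seeds", {
  for (seed in 1:3) {
    mesh <- generate_fixture("asymmetric_octahedron", min_edge_bp = 63L,
                             seed = seed)
    scaled <- scale_mesh(mesh, 63L)
    g <- build_graph(scaled)
    rt <- route_scaffold(g, spanning_tree(g), scaled)
    # cycle-count oracle over the base-node graph: follow down links
    nodes <- rt$nodes
    seen <- logical(nrow(nodes))
    cur <- 1L
    n <- 0L
    repeat {
      if (seen[cur]) break
      seen[cur] <- TRUE
      n <- n + 1L
      cur <- nodes$down[cur]
    }
    expect_equal(n, nrow(nodes))         # one cycle covers every node
    expect_equal(n, 2L * sum(scaled$edge_bp))
  }
})

test_that("vertex gaps reproduce an independent geometric oracle", {
  mesh <- generate_fixture("octahedron")
  scaled <- scale_mesh(mesh, 63L)
  g <- build_graph(scaled)
  rt <- insert_vertex_gaps(route_scaffold(g, spanning_tree(g), scaled),
                           scaled)
  cst <- dx_constants()

  # oracle: recompute each corner gap from the helix-placement rules
  v_nm <- scaled$vertices_nm
  centroid <- function(fi) colMeans(v_nm[mesh$faces[[fi]], , drop = FALSE])
  duplex_end <- function(e, fi, at_entry) {
    vv <- mesh$edges[e, ]
    p1 <- v_nm[vv[1L], ]; p2 <- v_nm[vv[2L], ]
    d12 <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    mid <- (p1 + p2) / 2
    fids <- c(g$arcs$face1[e], g$arcs$face2[e])
    tv <- lapply(fids, function(f) {
      t0 <- centroid(f) - mid
      t0 <- t0 - sum(t0 * d12) * d12
      t0 / sqrt(sum(t0^2))
    })
    bis <- tv[[1L]] - tv[[2L]]
    bis <- bis / sqrt(sum(bis^2))
    off <- (if (fi == fids[1L]) 1 else -1) * cst$interhelix_spacing / 2 * bis
    # face winding fixes scaffold direction on this duplex
    f <- mesh$faces[[if (fi == fids[1L]) fids[1L] else fids[2L]]]
    pos <- match(vv[1L], f)
    fwd <- f[pos %% length(f) + 1L] == vv[2L]
    dir <- if (fwd) d12 else -d12
    n <- scaled$edge_bp[e]
    start <- mid - n * cst$rise_per_bp / 2 * dir + off +
      cst$rise_per_bp / 2 * dir
    if (at_entry) start else start + (n - 1L) * cst$rise_per_bp * dir
  }
  runs <- rt$vertex_runs
  for (i in seq_len(nrow(runs))) {
    a <- duplex_end(runs$edge_in[i], runs$face[i], at_entry = FALSE)
    b <- duplex_end(runs$edge_out[i], runs$face[i], at_entry = TRUE)
    gap <- sqrt(sum((a - b)^2))
    expect_equal(runs$count[i], round(gap / cst$ssdna_len_per_nt))
  }
  expect_equal(rt$total_unpaired_nt, sum(runs$count))
  expect_equal(rt$required_scaffold_nt,
               rt$total_paired_nt + rt$total_unpaired_nt)
})

test_that("scaffold selection is a step function at 7249 and 48502", {
  expect_equal(select_scaffold(7249L)$name, "M13mp18")
  expect_equal(select_scaffold(7250L)$name, "Lambda")
  expect_equal(select_scaffold(48502L)$name, "Lambda")
  expect_equal(select_scaffold(48503L)$name, "random")
  expect_equal(select_scaffold(7248L)$name, "M13mp18")
  expect_equal(select_scaffold(48501L)$name, "Lambda")
  # lengths of the bundled records
  expect_equal(select_scaffold(7249L)$length, 7249L)
  expect_equal(select_scaffold(7250L)$length, 48502L)
  # random branch: reproducible and of exact length
  r1 <- select_scaffold(48503L, seed = 5L)
  r2 <- select_scaffold(48503L, seed = 5L)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(r1$length, 48503L)
  expect_false(identical(select_scaffold(48503L, seed = 6L)$sequence,
                         r1$sequence))
})

test_that("user scaffolds override selection with strict validation", {
  s <- select_scaffold(10L, user_seq = "ACGTACGTACGT")
  expect_equal(s$name, "user")
  expect_error(select_scaffold(20L, user_seq = "ACGT"),
               class = "dx_scaffold_length_error")
  expect_error(select_scaffold(4L, user_seq = "ACGN"),
               class = "dx_alphabet_error")
  expect_error(select_scaffold(0L), class = "dx_bounds_error")
})

test_that("sequence assignment is deterministic with excess bookkeeping", {
  d <- small_design("tetrahedron", 42L)
  rt <- d$route
  expect_equal(rt$excess_loop_nt, 0L)
  expect_equal(sum(is.na(rt$nodes$base)), 0L)

  # identical inputs -> byte-identical assignment
  d2 <- {
    mesh <- generate_fixture("tetrahedron")
    scaled <- scale_mesh(mesh, 42L)
    g <- build_graph(scaled)
    tr <- spanning_tree(g)
    r <- insert_vertex_gaps(route_scaffold(g, tr, scaled), scaled)
    assign_sequence(r, select_scaffold(
      r$required_scaffold_nt,
      user_seq = exact_scaffold(r$required_scaffold_nt)))
  }
  expect_identical(d2$nodes$base, rt$nodes$base)

  # M13 on the tetrahedron: excess = 7249 - required
  r3 <- insert_vertex_gaps(route_scaffold(d$graph, d$tree, d$scaled),
                           d$scaled)
  r3 <- assign_sequence(r3, select_scaffold(r3$required_scaffold_nt))
  expect_equal(r3$excess_loop_nt, 7249L - r3$required_scaffold_nt)
  expect_equal(length(r3$order),
               r3$required_scaffold_nt + r3$excess_loop_nt)
})
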