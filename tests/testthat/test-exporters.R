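test_that("hybrid encoders reproduce the boundary codes and capacities", {
  expect_equal(encode_atom_serial(99999), "99999")
  expect_equal(encode_atom_serial(100000), "A0000")
  expect_equal(encode_residue_number(9999), "9999")
  expect_equal(encode_residue_number(10000), "A000")
  lim <- pdb_limits()
  expect_equal(lim$hybrid_atom_capacity, 99999 + 52 * 36^4)
  expect_equal(52 * 36^4, 87340032)
  expect_equal(lim$hybrid_residue_capacity, 9999 + 52 * 36^3)
  expect_equal(52 * 36^3, 2426112)
  expect_error(encode_atom_serial(99999 + 52 * 36^4 + 1),
               class = "dx_capacity_error")
  expect_error(encode_residue_number(9999 + 52 * 36^3 + 1),
               class = "dx_capacity_error")
  expect_error(encode_atom_serial(0), class = "dx_capacity_error")
  # last codes of each alphabet half
  expect_equal(encode_atom_serial(100000 + 26 * 36^4), "a0000")
  expect_equal(encode_atom_serial(99999 + 52 * 36^4), "zZZZZ")
})

test_that("encoders are bijective and lexicographically monotone", {
  lim <- pdb_limits()
  probes <- c(1, 2, 99998, 99999, 100000, 100001,
              99999 + 52 * 36^4,
              dxwire:::with_seed(11, sort(sample(
                lim$hybrid_atom_capacity, 10000))))
  enc <- encode_atom_serial(probes)
  expect_equal(decode_atom_serial(enc), probes)
  rp <- c(1, 9999, 10000, 9999 + 52 * 36^3,
          dxwire:::with_seed(12, sort(sample(
            lim$hybrid_residue_capacity, 5000))))
  expect_equal(decode_residue_number(encode_residue_number(rp)), rp)
  # monotonicity within each regime and exhaustively at the boundary
  window <- 99990:100010
  encw <- encode_atom_serial(window)
  ord <- order(substr(encw, 1L, 1L) %in% c(LETTERS, letters), encw)
  expect_equal(encw[ord], encw)  # hybrid sorts after decimal, then lexic.
  expect_true(all(diff(decode_atom_serial(encw)) == 1))
  hy <- encode_atom_serial(sort(dxwire:::with_seed(
    13, sample(100000:(99999 + 52 * 36^4), 2000))))
  # within the hybrid regime, C-locale lexicographic order = numeric order
  expect_true(!is.unsorted(hy))
})

test_that("PDB writer round-trips atoms exactly", {
  aa <- small_atoms("tetrahedron", 42L)
  f <- tempfile(fileext = ".pdb")
  write_pdb(aa, f, provenance = "round-trip test")
  back <- read_pdb(f)
  expect_equal(nrow(back), nrow(aa$atoms))
  expect_equal(back$atom, aa$atoms$atom)
  expect_equal(back$residue, aa$atoms$residue)
  expect_equal(back$element, aa$atoms$element)
  expect_equal(back$x, round(aa$atoms$x, 3))
  expect_equal(back$y, round(aa$atoms$y, 3))
  expect_equal(back$z, round(aa$atoms$z, 3))
  expect_true(all(diff(back$serial) > 0))
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "TER")), nrow(aa$strands))
  # fixed-column check on one record
  rec <- lines[startsWith(lines, "ATOM")][1L]
  expect_equal(nchar(rec), 78L)
  expect_equal(substr(rec, 22L, 22L), "A")
})

test_that("PDB coordinate bounds are enforced", {
  aa <- small_atoms("tetrahedron", 42L)
  shifted <- aa
  shifted$atoms <- data.table::copy(aa$atoms)
  shifted$atoms$x <- shifted$atoms$x - 5000
  expect_error(write_pdb(shifted, tempfile(fileext = ".pdb")),
               "recentre", class = "dx_bounds_error")
})

test_that("chain identifiers wrap beyond 62 strands with a sidecar map", {
  # synthetic structure: 63 single-atom strands
  n <- 63L
  at <- data.table::data.table(
    serial = seq_len(n), strand = seq_len(n), strand_role = "staple",
    resseq = 1L, residue = "DA", atom = "P", element = "P",
    x = as.numeric(seq_len(n)), y = 0, z = 0, node = seq_len(n))
  toy <- list(atoms = at,
              strands = data.table::data.table(
                strand = seq_len(n), role = "staple", n_res = 1L))
  class(toy) <- "dx_atoms"
  f <- tempfile(fileext = ".pdb")
  write_pdb(toy, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "TER")), 63L)
  chains <- substr(lines[startsWith(lines, "ATOM")], 22L, 22L)
  expect_equal(chains[63L], chains[1L])      # wrapped
  expect_equal(length(unique(chains)), 62L)
  map <- utils::read.csv(paste0(f, ".strandmap.csv"))
  expect_equal(nrow(map), 63L)
  expect_equal(map$chain[63L], map$chain[1L])

  # multimodel flag: one MODEL per strand
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(toy, f2, multimodel = TRUE)
  l2 <- readLines(f2)
  expect_equal(sum(startsWith(l2, "MODEL")), 63L)
  expect_equal(sum(startsWith(l2, "ENDMDL")), 63L)
})

test_that("caDNAno export is reciprocal and closes the scaffold walk", {
  d <- small_design("tetrahedron", 42L)
  f <- tempfile(fileext = ".json")
  write_cadnano(d$staples, f)
  doc <- jsonlite::read_json(f)
  # helix count = 2 x E
  expect_equal(length(doc$vstrands), 2L * nrow(d$mesh$edges))
  # all arrays padded to the same multiple-of-21 length
  lens <- vapply(doc$vstrands, function(v) length(v$scaf), integer(1L))
  expect_true(all(lens == lens[1L]) && lens[1L] %% 21L == 0L)
  expect_true(cadnano_reciprocal(doc))
  walk <- dxwire:::cadnano_scaffold_walk_loops(doc)
  expect_equal(walk$steps, d$route$total_paired_nt)
  expect_equal(walk$steps_with_loops, d$route$required_scaffold_nt)
  # parity convention: num %% 2 == (row + col) %% 2
  for (v in doc$vstrands)
    expect_equal(v$num %% 2L, (v$row + v$col) %% 2L)
  # sidecar cross-section map
  xs <- utils::read.csv(paste0(f, ".crosssection.csv"))
  expect_equal(nrow(xs), 2L * nrow(d$mesh$edges))
  expect_setequal(xs$helix_num, 0:(2L * nrow(d$mesh$edges) - 1L))
})

test_that("cylinder model renders 2 nm cylinders per duplex", {
  sc <- scale_mesh(generate_fixture("tetrahedron"), 42L)
  fr <- place_helices(sc)
  f <- tempfile(fileext = ".ply")
  write_cylinder_model(sc, fr, f)
  lines <- readLines(f)
  meta <- grep("^comment cylinder", lines, value = TRUE)
  expect_equal(length(meta), 2L * nrow(sc$mesh$edges))
  expect_true(all(grepl("diameter_nm 2.0", meta)))
  expect_true(all(grepl("length_nm 13.94", meta)))
  # geometry re-parses as a valid PLY (per-cylinder closed prisms)
  header_v <- as.integer(sub(".*vertex (\\d+).*", "\\1",
                             grep("element vertex", lines, value = TRUE)))
  expect_equal(header_v, 2L * nrow(sc$mesh$edges) * 24L)
})

test_that("staple CSV round-trips and assigns 96-well plates", {
  d <- small_design("tetrahedron", 42L)
  f <- tempfile(fileext = ".csv")
  write_staple_csv(d$staples, f, plate_layout = TRUE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_identical(back$sequence_5to3, d$staples$staples$sequence_5to3)
  expect_equal(back$well[1L], "A1")
  expect_equal(back$well[13L], "B1")
  # synthetic 97-staple set: plate 2 starts at A1
  fake <- d$staples
  fake$staples <- data.table::rbindlist(
    rep(list(d$staples$staples), 5L))[1:97]
  fake$staples$staple_id <- 1:97
  f2 <- tempfile(fileext = ".csv")
  write_staple_csv(fake, f2, plate_layout = TRUE)
  b2 <- utils::read.csv(f2)
  expect_equal(b2$plate[96L], 1L)
  expect_equal(b2$well[96L], "H12")
  expect_equal(b2$plate[97L], 2L)
  expect_equal(b2$well[97L], "A1")
})
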