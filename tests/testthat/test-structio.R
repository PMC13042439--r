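# Structure I/O, fragment maps and minimum-distance profiles.

random_structure <- function(n, seed) {
  withr::with_seed(seed, suppressWarnings(structure_from_atoms(
    data.frame(element = sample(c("C", "N", "O", "Si"), n, replace = TRUE),
               x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8),
               resno = rep(seq_len(ceiling(n / 5)), each = 5)[seq_len(n)])
  )))
}

test_that("a minimal XYZ file reads as one atom at the origin", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "minimal", "H 0 0 0"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "H")
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
})

test_that("write/read round-trips preserve coordinates per format precision", {
  s <- random_structure(10, 7)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, xyz)
  write_structure(s, pdb)
  s_xyz <- read_structure(xyz)
  s_pdb <- read_structure(pdb)
  expect_equal(s_xyz$atoms$element, s$atoms$element)
  expect_equal(s_pdb$atoms$element, s$atoms$element)
  for (col in c("x", "y", "z")) {
    expect_equal(s_xyz$atoms[[col]], s$atoms[[col]], tolerance = 1e-6)
    expect_lt(max(abs(s_pdb$atoms[[col]] - s$atoms[[col]])), 1e-3 + 1e-9)
  }
  expect_equal(s_pdb$atoms$resno, s$atoms$resno)
})

test_that("altloc conformers other than blank/A are dropped", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      3  N   ALA A   2       2.000   0.000   0.000  1.00 10.00           N",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(0, 2))
})

test_that("malformed records raise parse errors naming the line", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad", "END"), pdb)
  expect_error(read_structure(pdb), "line 1")
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "H 0 0 0", "H 1 x 0"), xyz)
  expect_error(read_structure(xyz), "line 4")
  expect_error(read_structure("no/such/file.xyz"), "not found")
})

test_that("by-residue fragmentation flags guest HETATM and groups residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00 10.00           C",
    "HETATM    4  C1  LIG B   3       6.000   0.000   0.000  1.00 10.00           C",
    "HETATM    5  N1  LIG B   3       7.000   0.000   0.000  1.00 10.00           N",
    "END"), path)
  s <- read_structure(path)
  fm <- build_fragment_map(s, "by_residue", guest = "LIG")
  expect_equal(nrow(fm), 3)
  expect_equal(fm$role, c("host", "host", "guest"))
  expect_equal(fm$atoms[[1]], c(1L, 2L))
  expect_equal(fm$atoms[[3]], c(4L, 5L))
  expect_error(build_fragment_map(s, "by_residue", guest = "XXX"),
               "no fragment matched")
})

test_that("explicit fragmentation validates the partition", {
  s <- random_structure(6, 2)
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(list(atoms = 1:3),
                                           list(atoms = 4:6)))
  expect_equal(nrow(fm), 2)
  expect_equal(sum(lengths(fm$atoms)), 6)
  expect_error(
    build_fragment_map(s, "explicit",
                       explicit = list(list(atoms = 1:3), list(atoms = 3:6))),
    "more than one fragment")
  expect_error(
    build_fragment_map(s, "explicit",
                       explicit = list(list(atoms = 1:3), list(atoms = 4:5))),
    "not covered")
})

test_that("by-residue fragment contents are insensitive to atom order", {
  s <- random_structure(15, 9)
  fm0 <- build_fragment_map(s, "by_residue")
  key0 <- lapply(fm0$atoms, function(ix) sort(s$atoms$serial[ix]))
  for (seed in 1:3) {
    perm <- withr::with_seed(seed, sample(15))
    s2 <- structure_from_atoms(s$atoms[perm, , drop = FALSE])
    fm2 <- build_fragment_map(s2, "by_residue")
    key2 <- lapply(fm2$atoms, function(ix) sort(s2$atoms$serial[ix]))
    expect_setequal(vapply(key2, paste, "", collapse = ","),
                    vapply(key0, paste, "", collapse = ","))
  }
})

test_that("fragment map JSON round-trips with 0-based atoms on disk", {
  s <- random_structure(8, 4)
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(
                             list(atoms = c(1, 3, 5), role = "host"),
                             list(atoms = c(2, 4), role = "guest",
                                  formal_charge = 1),
                             list(atoms = c(6, 7, 8), role = "solvent")))
  path <- withr::local_tempfile(fileext = ".json")
  write_fragment_map(fm, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sort(unlist(raw$fragments$atoms)), 0:7)
  fm2 <- read_fragment_map(path, n_atoms = 8)
  expect_equal(fm2$atoms, fm$atoms)
  expect_equal(fm2$role, fm$role)
  expect_equal(fm2$formal_charge, fm$formal_charge)
})

test_that("minimum distances: 3-4-5 triangle, guest self-distance, brute force", {
  s <- suppressWarnings(structure_from_atoms(
    data.frame(element = c("C", "C"), x = c(0, 3), y = c(0, 4), z = 0)))
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(list(atoms = 1, role = "host"),
                                           list(atoms = 2, role = "guest")))
  prof <- min_distance_profile(s, fm)
  expect_equal(prof$rmin, c(5, 0))

  s50 <- random_structure(50, 31)
  fm50 <- build_fragment_map(
    s50, "explicit",
    explicit = c(lapply(split(1:40, rep(1:8, each = 5)),
                        function(ix) list(atoms = ix, role = "host")),
                 list(list(atoms = 41:50, role = "guest"))))
  prof50 <- min_distance_profile(s50, fm50)
  xyz <- as.matrix(s50$atoms[, c("x", "y", "z")])
  for (k in 1:8) {
    ix <- fm50$atoms[[k]]
    brute <- Inf
    for (i in ix) for (j in 41:50) {
      brute <- min(brute, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
    expect_equal(prof50$rmin[k], brute, tolerance = 1e-12)
  }
})

test_that("R_min is rigid-motion invariant and never grows when atoms join a fragment", {
  s <- random_structure(30, 13)
  fm <- build_fragment_map(
    s, "explicit",
    explicit = list(list(atoms = 1:10, role = "host"),
                    list(atoms = 11:20, role = "host"),
                    list(atoms = 21:30, role = "guest")))
  p0 <- min_distance_profile(s, fm)
  for (seed in 4:5) {
    p1 <- min_distance_profile(rigid_motion(s, seed), fm)
    expect_equal(p1$rmin, p0$rmin, tolerance = 1e-9)
  }
  fm_bigger <- build_fragment_map(
    s, "explicit",
    explicit = list(list(atoms = 1:20, role = "host"),
                    list(atoms = 21:30, role = "guest")))
  p2 <- min_distance_profile(s, fm_bigger)
  expect_lte(p2$rmin[1], min(p0$rmin[1:2]) + 1e-12)
})

test_that("partition completeness holds for every constructed map", {
  for (seed in 1:5) {
    s <- random_structure(20, seed)
    fm <- build_fragment_map(s, "by_residue")
    expect_equal(sum(lengths(fm$atoms)), nrow(s$atoms))
    expect_equal(sort(unlist(fm$atoms)), seq_len(nrow(s$atoms)))
  }
})

test_that("extract_fragments carries atoms and summed formal charge", {
  s <- random_structure(10, 6)
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(
                             list(atoms = 1:4, role = "host"),
                             list(atoms = 5:10, role = "guest",
                                  formal_charge = 1)))
  g <- extract_fragments(s, fm, 2)
  expect_equal(nrow(g$atoms), 6)
  expect_equal(g$net_charge, 1)
  expect_error(extract_fragments(s, fm, 99), "unknown fragment")
})
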