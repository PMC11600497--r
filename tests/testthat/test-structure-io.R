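test_that("PDB round trip preserves coordinates to 1e-3 angstrom", {
  z <- fx_zipper(2, "VIGLSA")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(z, path)
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), nrow(z$atoms))
  expect_lt(max(abs(stericzipper:::coords_of(m$atoms) -
                      stericzipper:::coords_of(z$atoms))), 1e-3 + 1e-9)
  expect_equal(m$cell, z$cell, tolerance = 1e-3)
})

test_that("files without cell records are rejected with a clear error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), path)
  expect_error(load_structure(path), "missing unit cell")
  expect_error(load_structure("no/such/file.pdb"), "not found")
})

test_that("minimal mmCIF input parses cell, space group and atoms", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a    20.000",
    "_cell.length_b    21.000",
    "_cell.length_c    22.000",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.458 2.000 3.000 1.00 10.00 ? 1 ALA A CA 1"), path)
  m <- load_structure(path)
  expect_equal(m$cell[1:3], c(20, 21, 22))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[2], 2.458)
})

test_that("symmetry-operator strings parse to correct fractional operators", {
  op <- stericzipper:::parse_symop_xyz("-x,y+1/2,-z")
  expect_equal(op$R, diag(c(-1, 1, -1)))
  expect_equal(op$t, c(0, 0.5, 0))
  ops <- stericzipper:::spacegroup_ops("P 21 21 21")
  expect_length(ops, 4)
  expect_equal(ops[[1]]$R, diag(3))
})

test_that("sanitize removes hydrogens, collapses altlocs, and is idempotent", {
  z <- fx_zipper(2, "VIGLSA")
  a <- z$atoms
  h <- a[1, ]; h$name <- "H"; h$elem <- "H"
  a2 <- a[1, ]; a2$altloc <- "B"; a2$occ <- 0.4
  a$altloc[1] <- "A"; a$occ[1] <- 0.6
  m <- crystal_model(rbind(a, h, a2), z$cell)
  s <- sanitize(m)
  expect_false(any(s$atoms$elem %in% c("H", "D")))
  expect_identical(sum(s$atoms$name == a$name[1] &
                         s$atoms$resno == a$resno[1] &
                         s$atoms$chain == a$chain[1]), 1L)
  expect_true(all(s$atoms$altloc == ""))
  expect_equal(s$atoms$occ[1], 0.6)  # highest-occupancy conformer kept
  expect_identical(sanitize(s)$atoms, s$atoms)
})

test_that("altloc ties resolve to the alphabetically first conformer", {
  z <- fx_zipper(2, "VIGLSA")
  a <- z$atoms[1:2, ]
  b <- a[1, ]
  a$altloc[1] <- "B"; b$altloc <- "A"
  a$occ[1] <- 0.5; b$occ <- 0.5
  b$x <- b$x + 1
  s <- sanitize(crystal_model(rbind(a, b), z$cell))
  kept <- s$atoms[s$atoms$name == a$name[1] & s$atoms$resno == a$resno[1], ]
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$x, b$x)
})

test_that("symmetry expansion preserves internal chain geometry", {
  z <- fx_zipper(2, "VIGLSA")
  lat <- expand_symmetry(sanitize(z), radius = 8)
  expect_true(any(lat$copies$identity))
  a <- lat$atoms
  ref <- a[a$copy == lat$copies$copy[lat$copies$identity][1], ]
  ref_d <- dist(stericzipper:::coords_of(ref))
  same_chain <- lat$copies$copy[lat$copies$chain == ref$chain[1]]
  for (k in same_chain) {
    cp <- a[a$copy == k, ]
    expect_lt(max(abs(dist(stericzipper:::coords_of(cp)) - ref_d)), 1e-6)
  }
})

test_that("a tiny expansion radius around an isolated molecule returns only identity copies", {
  s <- build_ideal_strand("AAAA")
  m <- crystal_model(s, c(100, 100, 100, 90, 90, 90))
  lat <- expand_symmetry(m, radius = 0.1)
  expect_identical(nrow(lat$copies), 1L)
  expect_true(all(lat$copies$identity))
})

test_that("expansion of a zipper cell recovers the designed sheet continuation", {
  z <- fx_zipper(2, "VIGLSA")
  lat <- expand_symmetry(sanitize(z), radius = 8)
  # the P1 cell holds one repeating unit per sheet; translations along the
  # sheet axis must continue each sheet to at least 5 strands (-2..+2)
  gt <- attr(z, "groundtruth")
  for (ch in unlist(gt$sheet_chains)) {
    expect_gte(sum(lat$copies$chain == ch), 5)
  }
  # no duplicated copies
  ctrs <- t(vapply(split(lat$atoms, lat$atoms$copy),
                   function(d) colMeans(stericzipper:::coords_of(d)),
                   numeric(3)))
  expect_identical(anyDuplicated(round(ctrs, 3)), 0L)
})
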