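test_that("ideal hexapeptide sheets have the canonical H-bond counts", {
  # interior chain of an ideal in-register hexapeptide sheet: 10 backbone
  # H-bonds for parallel, 12 for antiparallel arrangement
  expect_identical(interior_chain_hbonds(fx_parallel_sheet()), 10L)
  expect_identical(interior_chain_hbonds(fx_antiparallel_sheet()), 12L)
})

test_that("H-bond detection respects distance limits and chain identity", {
  # two chains far apart share no H-bonds
  s1 <- build_ideal_strand("AAAAAA", chain = "A")
  s2 <- build_ideal_strand("AAAAAA", chain = "B")
  s2$x <- s2$x + 20
  m <- crystal_model(rbind(s1, s2), c(99, 99, 99, 90, 90, 90))
  expect_identical(nrow(detect_backbone_hbonds(m)), 0L)
})

test_that("sheets assemble into ordered strands with correct arrangement", {
  for (arr in c("parallel", "antiparallel")) {
    sh <- if (arr == "parallel") fx_parallel_sheet() else
      fx_antiparallel_sheet()
    hb <- detect_backbone_hbonds(sh)
    sheets <- assemble_sheets(sh, hb)
    expect_length(sheets, 1)
    s <- sheets[[1]]
    expect_identical(s$arrangement, arr)
    expect_equal(s$mean_strand_spacing, 4.8, tolerance = 0.1)
    expect_equal(sum(s$axis_y * s$axis_x), 0, tolerance = 1e-9)
    # isolated chains do not join any sheet
    expect_length(s$copies, length(unique(sh$atoms$chain)))
  }
})

test_that("facial analysis separates the two faces by residue parity", {
  sh <- build_sheet(sheet_spec("LYIQWL", n_strands = 3,
                               arrangement = "parallel"))
  sheets <- assemble_sheets(sh, detect_backbone_hbonds(sh))
  fa <- facial_analysis(sheets[[1]])
  expect_identical(fa$facial_type, "antifacial")
  faces <- list(fa$positions_pos, fa$positions_neg)
  odd <- faces[[which(vapply(faces, function(f) 1 %in% f, logical(1)))]]
  expect_identical(odd, c(1L, 3L, 5L))      # Leu1, Ile3, Trp5
  even <- setdiff(1:6, odd)
  expect_identical(sort(unlist(faces)), 1:6)
  expect_identical(even, c(2L, 4L, 6L))     # Tyr2, Gln4, Leu6
})

test_that("equifacial and antifacial sheets are told apart", {
  sheets <- assemble_sheets(fx_antiparallel_sheet(),
                            detect_backbone_hbonds(fx_antiparallel_sheet()))
  expect_identical(sheets[[1]]$facial_type, "equifacial")  # homopolymer
  shq <- fx("aqaqaq_anti", function()
    build_sheet(sheet_spec("AQAQAQ", n_strands = 4,
                           arrangement = "antiparallel")))
  sq <- assemble_sheets(shq, detect_backbone_hbonds(shq))[[1]]
  expect_identical(sq$facial_type, "antifacial")
  types <- list(unique(as.character(sq$face_pos$resname)),
                unique(as.character(sq$face_neg$resname)))
  expect_setequal(vapply(types, paste, character(1)), c("ALA", "GLN"))
})

test_that("all eight constructible topology classes round-trip", {
  for (cl in 1:8) {
    z <- fx_zipper(cl, "LYIQWL")
    pl <- fx_pipeline(paste0(cl, "_LYIQWL"), z)
    si <- identity_sheet_pair(pl)
    lab <- assign_topology_class(pl$sheets[[si[1]]], pl$sheets[[si[2]]],
                                 pl$lat, pl$hb)
    expect_identical(lab$class_id, as.integer(cl))
    expect_identical(lab$arrangement,
                     if (cl <= 4) "parallel" else "antiparallel")
    expect_false(lab$oor)
    expect_false(lab$larks)
    # parallel implies class 1-4, antiparallel 5-8
    expect_true(lab$class_id %in% (if (lab$arrangement == "parallel") 1:4
                                   else 5:8))
  }
})

test_that("class assignment is invariant to rigid motion and sheet swap", {
  z <- fx_zipper(3, "LYIQWL")
  pl <- fx_pipeline("3_LYIQWL", z)
  si <- identity_sheet_pair(pl)
  lab <- assign_topology_class(pl$sheets[[si[1]]], pl$sheets[[si[2]]],
                               pl$lat, pl$hb)
  swapped <- assign_topology_class(pl$sheets[[si[2]]], pl$sheets[[si[1]]],
                                   pl$lat, pl$hb)
  expect_identical(swapped$class_id, lab$class_id)

  # rigid-body motion of the whole lattice
  R <- stericzipper:::rotation_matrix(c(1, 1, 0), 35)
  lat2 <- pl$lat
  xyz <- stericzipper:::coords_of(lat2$atoms) %*% t(R)
  lat2$atoms <- stericzipper:::set_coords(lat2$atoms,
                                          sweep(xyz, 2, -c(3, -7, 11)))
  sheets2 <- assemble_sheets(lat2, detect_backbone_hbonds(lat2))
  idc <- lat2$copies$copy[lat2$copies$identity]
  si2 <- which(vapply(sheets2, function(s) any(s$copies %in% idc),
                      logical(1)))
  lab2 <- assign_topology_class(sheets2[[si2[1]]], sheets2[[si2[2]]], lat2)
  expect_identical(lab2$class_id, lab$class_id)
})

test_that("mixed parallel/antiparallel pairs are reported unclassified", {
  shp <- fx_parallel_sheet(); sha <- fx_antiparallel_sheet()
  sp <- assemble_sheets(shp, detect_backbone_hbonds(shp))[[1]]
  sa <- assemble_sheets(sha, detect_backbone_hbonds(sha))[[1]]
  lab <- assign_topology_class(sp, sa, shp)
  expect_true(is.na(lab$class_id))
})

test_that("out-of-register sheets are detected with their shift", {
  inreg <- assemble_sheets(fx_parallel_sheet(),
                           hb0 <- detect_backbone_hbonds(fx_parallel_sheet()))
  r0 <- detect_out_of_register(inreg[[1]], hb0)
  expect_false(r0$oor); expect_identical(r0$shift, 0L)
  expect_lt(r0$tilt, 5)

  for (arr in c("parallel", "antiparallel")) {
    sh <- build_sheet(sheet_spec("AAAAAA",
                                 n_strands = if (arr == "parallel") 5 else 6,
                                 arrangement = arr, register_shift = 1))
    hb <- detect_backbone_hbonds(sh)
    s <- assemble_sheets(sh, hb)[[1]]
    r <- detect_out_of_register(s, hb)
    expect_true(r$oor)
    expect_identical(r$shift, 1L)
    if (arr == "parallel") {
      # the shifted registry tilts strands off the sheet-axis perpendicular
      expect_gt(r$tilt, 10)
    }
  }
})

test_that("kinked chains raise the LARKS flag, ideal and edge cases do not", {
  expect_true(detect_larks(build_kinked_chain("AAAAAA", 3, -60, -40)))
  expect_false(detect_larks(build_ideal_strand("AAAAAA")))
  # a non-beta TERMINAL residue does not trigger the interior-only rule:
  # the terminal psi is undefined, so the chain stays unflagged
  term <- build_ideal_strand("AAAAAA", phi = c(-119, -119, -119, -119, -119, -60),
                             psi = c(113, 113, 113, 113, 113, -40))
  expect_false(detect_larks(term))
  expect_error(detect_larks(build_ideal_strand("AAA")), "short")
})
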