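test_that("contacting pairs are found by van der Waals + probe criterion", {
  z <- fx_zipper(1, "LYIQWL")
  pl <- fx_pipeline("1_LYIQWL", z)
  pairs <- find_contacting_pairs(pl$sheets, pl$lat)
  expect_gt(length(pairs), 0)
  # two isolated far-apart sheets are not candidates
  s1 <- build_sheet(sheet_spec("AAAAAA", n_strands = 3,
                               arrangement = "parallel"))
  a2 <- s1$atoms; a2$x <- a2$x + 30
  a2$chain <- tolower(a2$chain)
  m <- crystal_model(rbind(s1$atoms, a2), c(200, 200, 200, 90, 90, 90))
  lat <- stericzipper:::as_lattice(m)
  hb <- detect_backbone_hbonds(lat)
  sheets <- assemble_sheets(lat, hb)
  expect_length(sheets, 2)
  expect_length(find_contacting_pairs(sheets, lat), 0)
})

test_that("a class 1 zipper exposes its two distinct interfaces", {
  z <- fx_zipper(1, "LYIQWL")
  r <- fx("report_c1_LYIQWL", function()
    analyze_crystal(z, id = "c1"))
  expect_length(r$interfaces, 2)
  keys <- vapply(r$interfaces, function(i) i$residues_key, character(1))
  expect_length(unique(keys), 2)  # the odd-face and the even-face zipper
})

test_that("admission flips exactly at each of the four criteria thresholds", {
  z <- fx_zipper(1, "LYIQWL")
  pl <- fx_pipeline("1_LYIQWL", z)
  si <- identity_sheet_pair(pl)
  sa <- pl$sheets[[si[1]]]; sb <- pl$sheets[[si[2]]]
  base <- admit_interface(sa, sb, pl$lat, pl$hb, descriptors = FALSE)
  expect_true(base$admitted)
  slab <- select_slab(sa, sb, pl$lat)
  ab <- buried_area(slab)
  expect_gte(ab, 50)  # stated size limit honoured by every admitted interface

  # criterion (i): buried-area threshold straddled around the measured Ab
  lo <- admit_interface(sa, sb, pl$lat, pl$hb, min_buried_area = ab - 0.5,
                        descriptors = FALSE)
  hi <- admit_interface(sa, sb, pl$lat, pl$hb, min_buried_area = ab + 0.5,
                        descriptors = FALSE)
  expect_true(lo$admitted)
  expect_false(isTRUE(hi$admitted))
  expect_identical(hi$criterion, 1L)

  # criterion (iii): mean involved side chains per chain
  m <- base$mean_involved
  expect_gte(m, 1.5)
  hi3 <- admit_interface(sa, sb, pl$lat, pl$hb,
                         min_mean_side_chains = m + 0.01,
                         descriptors = FALSE)
  expect_false(isTRUE(hi3$admitted))
  expect_identical(hi3$criterion, 3L)

  # criteria (ii)+(iv): raising the involvement cutoff strips sparse
  # strands first (criterion 2), then the joint mean
  bur <- stericzipper:::residue_burial(slab)
  worst <- max(tapply(bur$side_chain_burial, bur$copy, max))
  hi2 <- admit_interface(sa, sb, pl$lat, pl$hb,
                         min_side_chain_burial = worst + 1,
                         min_gly_burial = worst + 1,
                         descriptors = FALSE)
  expect_false(isTRUE(hi2$admitted))
  expect_identical(hi2$criterion, 2L)
})

test_that("a wide-gap polyalanine pair fails the buried-area criterion", {
  z <- fx("wide_gap", function()
    build_zipper(zipper_spec(1, sheet_spec("AAAAAA", arrangement = "parallel"),
                             inter_sheet_gap = 6.5, lateral_offset = c(0, 0),
                             network = "1D")))
  pl <- fx_pipeline("wide_gap", z)
  si <- identity_sheet_pair(pl)
  r <- admit_interface(pl$sheets[[si[1]]], pl$sheets[[si[2]]], pl$lat, pl$hb,
                       descriptors = FALSE)
  expect_false(isTRUE(r$admitted))
  expect_identical(r$criterion, 1L)
})

test_that("deduplication averages descriptors and is idempotent", {
  mk <- function(sc, key = "1,3,5 : 1,3,5", class_id = 1L) {
    structure(list(admitted = TRUE,
                   residues_key = key,
                   residues_label = key,
                   topology = list(class_id = class_id),
                   descriptors = structure(list(Sc = sc, Ab = 100,
                                                SDi = 1.5),
                                           class = "descriptor_set"),
                   multiplicity = 1L),
              class = "zipper_interface")
  }
  two <- deduplicate(list(mk(0.80), mk(0.82)))
  expect_length(two, 1)
  expect_equal(two[[1]]$descriptors$Sc, 0.81)
  expect_identical(two[[1]]$multiplicity, 2L)
  # idempotent and order-independent
  again <- deduplicate(two)
  expect_equal(again[[1]]$descriptors$Sc, 0.81)
  expect_identical(again[[1]]$multiplicity, 2L)
  rev_order <- deduplicate(list(mk(0.82), mk(0.80)))
  expect_equal(rev_order[[1]]$descriptors$Sc, 0.81)
  # distinct classes stay distinct
  expect_length(deduplicate(list(mk(0.8), mk(0.8, class_id = 2L))), 2)
  # single observation unchanged
  one <- deduplicate(list(mk(0.7)))
  expect_equal(one[[1]]$descriptors$Sc, 0.7)
})

test_that("trapped solvent marks an interface partially wet", {
  z <- fx_zipper(1, "LYIQWL")
  r <- fx("report_c1_LYIQWL", function() analyze_crystal(z, id = "c1"))
  expect_true(all(vapply(r$interfaces, function(i) i$wet, character(1)) ==
                    "dry"))
  # a flat, slightly gapped zipper leaves room for a trapped water between
  # the facing surfaces (thresholds lowered: only the wetness rule is
  # under test here)
  zg <- fx("gapped_flat", function()
    build_zipper(zipper_spec(1, sheet_spec("LYIQWL", arrangement = "parallel"),
                             inter_sheet_gap = 4.8, lateral_offset = c(0, 0),
                             network = "1D")))
  pl <- fx_pipeline("gapped_flat", zg)
  si <- identity_sheet_pair(pl)
  iface <- admit_interface(pl$sheets[[si[1]]], pl$sheets[[si[2]]], pl$lat,
                           pl$hb, min_buried_area = 5,
                           min_side_chain_burial = 0.5, min_gly_burial = 0.5,
                           min_mean_side_chains = 0.5, descriptors = FALSE)
  expect_true(iface$admitted)
  A <- stericzipper:::slab_atoms(iface$slab, "a")
  B <- stericzipper:::slab_atoms(iface$slab, "b")
  y <- iface$slab$axis_y / sqrt(sum(iface$slab$axis_y^2))
  ca <- colMeans(stericzipper:::coords_of(A))
  cb <- colMeans(stericzipper:::coords_of(B))
  xd <- cb - ca; xd <- xd - sum(xd * y) * y; xd <- xd / sqrt(sum(xd^2))
  org <- (ca + cb) / 2
  px <- function(M) as.numeric((M %*% xd) - sum(org * xd))
  mid_x <- mean(c(max(px(stericzipper:::coords_of(A))),
                  min(px(stericzipper:::coords_of(B)))))
  wpos <- org + xd * mid_x
  add_w <- function(lat, pos) {
    w <- stericzipper:::new_atoms("O", "O", "HOH", 999L, "W",
                                  matrix(pos, 1, 3), het = TRUE)
    w$copy <- max(lat$atoms$copy) + 1L
    lat$atoms <- rbind(lat$atoms, w)
    lat
  }
  expect_identical(classify_wetness(iface, add_w(pl$lat, wpos)),
                   "partially_wet")
  # outside the footprint, beyond the rim: dry
  zdir <- stericzipper:::vcross(xd, y)
  expect_identical(classify_wetness(iface, add_w(pl$lat, wpos + 40 * zdir)),
                   "dry")
  # no solvent at all: dry
  expect_identical(classify_wetness(iface, pl$lat), "dry")
})
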