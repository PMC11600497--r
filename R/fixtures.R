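# Deterministic generator of ideal peptide beta-sheet crystals with known
# ground-truth topology. No randomness anywhere: identical arguments give
# identical coordinates.
#
# Conventions of the construction frame: strands run along z, strands of one
# sheet stack along y (the sheet/fibril axis), and two sheets of a zipper face
# each other along x. Models built with a unit cell are rotated at the end
# into the CRYST1 orthogonalization convention (a along x, b in the xy plane).

# Ideal backbone geometry (angstrom / degrees); standard peptide values.
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4, omega = 180
)

# Improper dihedral N-C-CA-CB for an L-amino acid (placing CB from refs
# N, C, CA); sign fixes the chirality.
.cb_improper <- 122.6

# Side-chain templates beyond CB: ideal extended rotamers, one atom per row,
# placed by natural extension from three previously placed atoms of the same
# residue. Covers the residue types used by the synthetic fixtures.
.sc_templates <- list(
  VAL = list(
    list("CG1", c("N","CA","CB"), 1.521, 110.5, 180),
    list("CG2", c("N","CA","CB"), 1.521, 110.5, -60)),
  LEU = list(
    list("CG",  c("N","CA","CB"), 1.530, 116.3, 180),
    list("CD1", c("CA","CB","CG"), 1.521, 110.7, 180),
    list("CD2", c("CA","CB","CG"), 1.521, 110.7, -60)),
  ILE = list(
    list("CG1", c("N","CA","CB"), 1.530, 110.4, 180),
    list("CG2", c("N","CA","CB"), 1.521, 110.5, -60),
    list("CD1", c("CA","CB","CG1"), 1.513, 113.8, 180)),
  SER = list(
    list("OG",  c("N","CA","CB"), 1.417, 111.1, 180)),
  ASN = list(
    list("CG",  c("N","CA","CB"), 1.516, 112.6, 180),
    list("OD1", c("CA","CB","CG"), 1.231, 120.8, -60),
    list("ND2", c("CA","CB","CG"), 1.328, 116.4, 120)),
  GLN = list(
    list("CG",  c("N","CA","CB"), 1.530, 114.1, 180),
    list("CD",  c("CA","CB","CG"), 1.516, 112.6, 180),
    list("OE1", c("CB","CG","CD"), 1.231, 120.8, 0),
    list("NE2", c("CB","CG","CD"), 1.328, 116.4, 180)),
  TYR = list(
    list("CG",  c("N","CA","CB"), 1.512, 113.9, 180),
    list("CD1", c("CA","CB","CG"), 1.389, 120.8, -30),
    list("CD2", c("CA","CB","CG"), 1.389, 120.8, 150),
    list("CE1", c("CB","CG","CD1"), 1.382, 121.2, 180),
    list("CE2", c("CB","CG","CD2"), 1.382, 121.2, 180),
    list("CZ",  c("CG","CD1","CE1"), 1.378, 119.6, 0),
    list("OH",  c("CD1","CE1","CZ"), 1.376, 119.9, 180)),
  TRP = list(
    list("CG",  c("N","CA","CB"), 1.498, 113.6, 180),
    list("CD1", c("CA","CB","CG"), 1.365, 126.9, -30),
    list("CD2", c("CA","CB","CG"), 1.433, 126.7, 150),
    list("NE1", c("CB","CG","CD1"), 1.374, 110.2, 180),
    list("CE2", c("CB","CG","CD2"), 1.409, 107.2, 180),
    list("CE3", c("CB","CG","CD2"), 1.398, 133.9, 0),
    list("CZ2", c("CG","CD2","CE2"), 1.394, 122.4, 180),
    list("CZ3", c("CG","CD2","CE3"), 1.382, 118.6, 180),
    list("CH2", c("CD2","CE2","CZ2"), 1.368, 117.5, 0))
)

.supported_residues <- c("GLY", "ALA", names(.sc_templates))

#' Build an ideal peptide strand from backbone dihedrals
#'
#' Places backbone atoms (N, CA, C, O) plus CB (non-Gly) and ideal extended
#' side chains for supported residue types, using standard peptide bond
#' lengths and angles. The recomputed (phi, psi) of interior residues equal
#' the request to within 0.5 degrees.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees; either scalars (applied to
#'   every residue) or vectors of per-residue values.
#' @param chain chain identifier for the returned atoms.
#' @return atom data.frame of one peptide chain.
#' @export
build_ideal_strand <- function(sequence, phi = -119, psi = 113, chain = "A") {
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) < 1) stop("empty sequence")
  res3 <- aa_three(seq1)
  bad <- setdiff(unique(res3), .supported_residues)
  if (length(bad)) stop("no side-chain template for residue(s): ",
                        paste(bad, collapse = ", "))
  n <- length(res3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  stopifnot(all(phi > -180 & phi <= 180), all(psi > -180 & psi <= 180))

  b <- .bb
  # backbone trace
  N <- vector("list", n); CA <- vector("list", n); C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b$n_ca, 0, 0)
  ang <- b$ang_n_ca_c * DEG
  C[[1]] <- CA[[1]] + b$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], b$c_n, b$ang_ca_c_n, psi[i])
      CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], b$n_ca, b$ang_c_n_ca, b$omega)
      C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], b$ca_c, b$ang_n_ca_c, phi[i + 1])
    }
  }

  name <- character(0); elem <- character(0); resname <- character(0)
  resno <- integer(0); xyz <- NULL
  add <- function(nm, el, rn, ri, p) {
    name <<- c(name, nm); elem <<- c(elem, el)
    resname <<- c(resname, rn); resno <<- c(resno, ri)
    xyz <<- rbind(xyz, p)
  }
  for (i in seq_len(n)) {
    add("N", "N", res3[i], i, N[[i]])
    add("CA", "C", res3[i], i, CA[[i]])
    add("C", "C", res3[i], i, C[[i]])
    # carbonyl O trans to the next N (dihedral psi + 180 about CA-C)
    O <- place_atom(N[[i]], CA[[i]], C[[i]], b$c_o, b$ang_ca_c_o, psi[i] + 180)
    add("O", "O", res3[i], i, O)
    if (res3[i] != "GLY") {
      placed <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
      placed$CB <- place_atom(placed$N, placed$C, placed$CA,
                              b$ca_cb, b$ang_n_ca_cb, .cb_improper)
      add("CB", "C", res3[i], i, placed$CB)
      for (tpl in .sc_templates[[res3[i]]]) {
        p <- place_atom(placed[[tpl[[2]][1]]], placed[[tpl[[2]][2]]],
                        placed[[tpl[[2]][3]]], tpl[[3]], tpl[[4]], tpl[[5]])
        placed[[tpl[[1]]]] <- p
        add(tpl[[1]], substr(tpl[[1]], 1, 1), res3[i], i, p)
      }
    }
  }
  new_atoms(name, elem, resname, resno, chain, xyz)
}

#' Build a kinked (LARKS-like) peptide chain
#'
#' All residues adopt the ideal beta conformation except one interior kink
#' residue at the stated dihedrals.
#'
#' @param sequence one-letter string.
#' @param kink_position interior residue index (2 .. length-1).
#' @param kink_phi,kink_psi dihedrals of the kink residue (degrees).
#' @param phi,psi dihedrals of the remaining residues.
#' @inheritParams build_ideal_strand
#' @return atom data.frame of one peptide chain.
#' @export
build_kinked_chain <- function(sequence, kink_position, kink_phi = -60,
                               kink_psi = -40, phi = -119, psi = 113,
                               chain = "A") {
  n <- nchar(sequence)
  if (kink_position < 2 || kink_position > n - 1)
    stop("kink_position must be an interior residue (2 .. length-1)")
  phiv <- rep(phi, n); psiv <- rep(psi, n)
  phiv[kink_position] <- kink_phi; psiv[kink_position] <- kink_psi
  build_ideal_strand(sequence, phiv, psiv, chain = chain)
}

# Rotate/translate a built strand into the construction frame: chain axis
# along +z, mean pleat (carbonyl) direction of even residues along +y,
# CA centroid at the origin.
orient_strand <- function(atoms) {
  xyz <- coords_of(atoms)
  ca <- xyz[atoms$name == "CA", , drop = FALSE]
  nres <- nrow(ca)
  if (nres >= 3) {
    ax <- colMeans(ca[3:nres, , drop = FALSE] - ca[1:(nres - 2), , drop = FALSE])
  } else {
    ax <- ca[nres, ] - ca[1, ]
  }
  ax <- unitv(ax)
  z <- c(0, 0, 1)
  v <- vcross(ax, z)
  if (vnorm(v) > 1e-9) {
    R1 <- rotation_matrix(v, acos(max(-1, min(1, sum(ax * z)))) / DEG)
  } else R1 <- if (sum(ax * z) > 0) diag(3) else rotation_matrix(c(1, 0, 0), 180)
  xyz <- xyz %*% t(R1)
  # azimuth: alternating carbonyl direction onto +y
  co <- xyz[atoms$name == "O", , drop = FALSE] - xyz[atoms$name == "C", , drop = FALSE]
  sgn <- (-1)^(seq_len(nrow(co)) - 1)
  v <- colSums(co * sgn)
  v[3] <- 0
  if (vnorm(v) > 1e-9) {
    angle <- atan2(v[1], v[2]) / DEG   # rotate so v -> +y
    xyz <- xyz %*% t(rotation_matrix(c(0, 0, 1), angle))
  }
  ctr <- colMeans(xyz[atoms$name == "CA", , drop = FALSE])
  set_coords(atoms, sweep(xyz, 2, ctr))
}

# Rise per residue along the strand axis of an oriented strand.
strand_rise <- function(atoms) {
  caz <- atoms$z[atoms$name == "CA"]
  (max(caz) - min(caz)) / (length(caz) - 1)
}

# Geometric backbone H-bond pairing between two atom tables: N...O distance
# and C=O...N angle criteria; returns one row per (donor N, acceptor O) pair.
hbond_pairs <- function(don, acc, d_max = 3.5, angle_min = 120, d_min = 2.2) {
  Nn <- don[don$name == "N", , drop = FALSE]
  Oo <- acc[acc$name == "O", , drop = FALSE]
  Cc <- acc[acc$name == "C", , drop = FALSE]
  if (!nrow(Nn) || !nrow(Oo)) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(Nn))) {
    np <- c(Nn$x[i], Nn$y[i], Nn$z[i])
    d <- sqrt((Oo$x - np[1])^2 + (Oo$y - np[2])^2 + (Oo$z - np[3])^2)
    hit <- which(d >= d_min & d <= d_max)
    for (j in hit) {
      k <- which(Cc$resno == Oo$resno[j])[1]
      if (is.na(k)) next
      ang <- bond_angle(c(Cc$x[k], Cc$y[k], Cc$z[k]),
                        c(Oo$x[j], Oo$y[j], Oo$z[j]), np)
      if (ang >= angle_min) {
        out <- rbind(out, data.frame(
          don_res = Nn$resno[i], acc_res = Oo$resno[j],
          distance = d[j], angle = ang))
      }
    }
  }
  out
}

# Score a candidate inter-strand geometry: number of good H-bonds, with a
# closeness-to-2.9-angstrom tie-break. Used only inside the deterministic
# construction scans.
.hb_score <- function(don, acc, both = TRUE) {
  h1 <- hbond_pairs(don, acc)
  h2 <- if (both) hbond_pairs(acc, don) else NULL
  h <- rbind(h1, h2)
  if (is.null(h)) return(0)
  nrow(h) + sum(exp(-((h$distance - 2.9) / 0.3)^2)) / (nrow(h) + 1)
}

translate_atoms <- function(atoms, t) {
  atoms$x <- atoms$x + t[1]; atoms$y <- atoms$y + t[2]; atoms$z <- atoms$z + t[3]
  atoms
}

rotate_atoms <- function(atoms, R) {
  set_coords(atoms, coords_of(atoms) %*% t(R))
}

#' Specification of an ideal beta-sheet
#'
#' @param sequence one-letter amino-acid string (length >= 3).
#' @param n_strands number of strands (>= 2; even for antiparallel sheets).
#' @param arrangement "parallel" or "antiparallel".
#' @param phi,psi backbone dihedrals (degrees).
#' @param strand_spacing distance between adjacent strand centroids along the
#'   sheet axis (angstrom, in (3.5, 7)).
#' @param register_shift integer residue offset between H-bonded neighbours
#'   (0 = in register).
#' @return a `sheet_spec` list.
#' @export
sheet_spec <- function(sequence, n_strands = 5,
                       arrangement = c("parallel", "antiparallel"),
                       phi = -119, psi = 113, strand_spacing = 4.8,
                       register_shift = 0) {
  arrangement <- match.arg(arrangement)
  stopifnot(nchar(sequence) >= 3, n_strands >= 2,
            strand_spacing > 3.5, strand_spacing < 7.0)
  if (arrangement == "antiparallel" && n_strands %% 2 != 0)
    n_strands <- n_strands + 1   # whole repeating units
  structure(list(sequence = sequence, n_strands = n_strands,
                 arrangement = arrangement, phi = phi, psi = psi,
                 strand_spacing = strand_spacing,
                 register_shift = as.integer(register_shift)),
            class = "sheet_spec")
}

# Internal: build the strand list of one sheet in the construction frame.
# Returns list(chains = list of atom tables, period = y-translation of one
# repeating unit, unit_size = strands per repeating unit).
build_sheet_chains <- function(spec, chain_ids) {
  base <- orient_strand(build_ideal_strand(spec$sequence, spec$phi, spec$psi))
  s <- spec$strand_spacing
  rise <- strand_rise(base)
  shift_z <- spec$register_shift * rise

  if (spec$arrangement == "parallel") {
    # neighbour = pure translation (0, s, shift_z); choose the strand azimuth
    # rho that best realizes the inter-strand H-bond geometry
    score_rho <- function(rho) {
      b <- rotate_atoms(base, rotation_matrix(c(0, 0, 1), rho))
      .hb_score(translate_atoms(b, c(0, s, shift_z)), b)
    }
    rhos <- seq(0, 358, by = 2)
    sc <- vapply(rhos, score_rho, numeric(1))
    rho <- rhos[which.max(sc)]
    fine <- seq(rho - 2, rho + 2, by = 0.25)
    rho <- fine[which.max(vapply(fine, score_rho, numeric(1)))]
    b0 <- rotate_atoms(base, rotation_matrix(c(0, 0, 1), rho))
    chains <- lapply(seq_len(spec$n_strands) - 1L, function(k) {
      a <- translate_atoms(b0, c(0, k * s, k * shift_z))
      a$chain <- chain_ids[k + 1]
      a
    })
    list(chains = chains, period = c(0, s, shift_z), unit_size = 1L,
         rho = rho, base = b0)
  } else {
    # alternating strand direction: odd strands are the base strand rotated
    # 180 degrees about x, with a z registry offset chosen by the same scan
    score <- function(rho, dz) {
      b <- rotate_atoms(base, rotation_matrix(c(0, 0, 1), rho))
      f <- rotate_atoms(b, rotation_matrix(c(1, 0, 0), 180))
      f1 <- translate_atoms(f, c(0, s, dz))
      b2 <- translate_atoms(b, c(0, 2 * s, 0))
      .hb_score(f1, b) + .hb_score(b2, f1)
    }
    # registry scan window: centred on the requested shift and, for a
    # requested out-of-register sheet, narrow enough to exclude the
    # in-register solution
    rise_off <- spec$register_shift * rise
    halfw <- if (spec$register_shift == 0) 3.5 else 1.5
    dzs <- seq(-halfw, halfw, by = 0.25) + rise_off
    rhos <- seq(0, 358, by = 4)
    best <- c(-Inf, 0, 0)
    for (rho in rhos) for (dz in dzs) {
      v <- score(rho, dz)
      if (v > best[1]) best <- c(v, rho, dz)
    }
    # local refinement
    for (step in c(1, 0.25)) {
      cand <- expand.grid(rho = best[2] + seq(-2, 2, by = step),
                          dz = best[3] + seq(-0.3, 0.3, by = 0.05))
      v <- mapply(score, cand$rho, cand$dz)
      i <- which.max(v)
      if (v[i] > best[1]) best <- c(v[i], cand$rho[i], cand$dz[i])
    }
    rho <- best[2]; dz <- best[3]
    b0 <- rotate_atoms(base, rotation_matrix(c(0, 0, 1), rho))
    f0 <- translate_atoms(rotate_atoms(b0, rotation_matrix(c(1, 0, 0), 180)),
                          c(0, s, dz))
    chains <- lapply(seq_len(spec$n_strands) - 1L, function(k) {
      a <- if (k %% 2 == 0) translate_atoms(b0, c(0, k * s, 0))
           else translate_atoms(f0, c(0, (k - 1) * s, 0))
      a$chain <- chain_ids[k + 1]
      a
    })
    list(chains = chains, period = c(0, 2 * s, 0), unit_size = 2L,
         rho = rho, dz = dz, base = b0, flipped = f0)
  }
}

#' Build an ideal beta-sheet
#'
#' Stacks ideal strands along the sheet axis (y in the construction frame) at
#' the requested spacing; the antiparallel arrangement alternates strand
#' direction. The relative azimuth and registry offset of the strands are
#' chosen by a deterministic scan that realizes inter-backbone H-bond
#' geometry (N...O about 2.9 angstrom) for in-register ideal specifications.
#'
#' @param spec a [sheet_spec()].
#' @param cell optional unit cell; by default a large P1 box enclosing the
#'   sheet (the sheet is finite, not lattice-continued).
#' @return a `crystal_model` with one chain per strand and a `groundtruth`
#'   attribute recording the construction parameters.
#' @export
build_sheet <- function(spec, cell = NULL) {
  built <- build_sheet_chains(spec, LETTERS[seq_len(spec$n_strands)])
  atoms <- do.call(rbind, built$chains)
  rownames(atoms) <- NULL
  if (is.null(cell)) {
    ext <- apply(coords_of(atoms), 2, function(v) diff(range(v)))
    cell <- c(ext + 40, 90, 90, 90)
  }
  m <- crystal_model(atoms, cell, "P 1")
  attr(m, "groundtruth") <- list(
    kind = "sheet", arrangement = spec$arrangement,
    n_strands = spec$n_strands, unit_size = built$unit_size,
    register_shift = spec$register_shift,
    axis_y = c(0, 1, 0), axis_x = c(1, 0, 0), spec = spec)
  m
}

#' Specification of a steric-zipper fixture crystal
#'
#' @param class_id topology class 1-8 (1-4 parallel, 5-8 antiparallel).
#' @param sheet_spec a [sheet_spec()]; its arrangement must match `class_id`.
#' @param inter_sheet_gap closest inter-atomic approach between the two
#'   sheets along x (angstrom, >= 3).
#' @param lateral_offset relative displacement of sheet B: a scalar z
#'   offset along the strand direction, or c(y, z) giving the offset along
#'   the sheet axis as well; NULL (default) selects the offset that best
#'   interdigitates the facing side chains, by a deterministic scan.
#' @param network target quaternary packing of the fixture crystal:
#'   "2D" (catemer of sandwiches along x), "1D" (isolated sandwich) or
#'   "3D" (brick pattern, x-steps sheared by half the chain length).
#' @return a `zipper_spec` list.
#' @export
zipper_spec <- function(class_id, sheet_spec, inter_sheet_gap = 3.8,
                        lateral_offset = NULL, network = c("2D", "1D", "3D")) {
  network <- match.arg(network)
  stopifnot(class_id %in% 1:8)
  par_class <- class_id <= 4
  if (par_class != (sheet_spec$arrangement == "parallel"))
    stop("class ", class_id, " requires ",
         if (par_class) "parallel" else "antiparallel", " sheets")
  if (inter_sheet_gap < 3) stop("geometrically impossible inter-sheet gap (< 3 angstrom)")
  structure(list(class_id = as.integer(class_id), sheet_spec = sheet_spec,
                 inter_sheet_gap = inter_sheet_gap,
                 lateral_offset = lateral_offset, network = network),
            class = "zipper_spec")
}

# Topology class combinatorics shared with the classifier: which rigid
# operation relates sheet B to sheet A for each class.
#   same face + same direction  -> classes 1 / 5
#   other face + same direction -> classes 2 / 6
#   same face + flipped         -> classes 3 / 7
#   other face + flipped        -> classes 4 / 8
.class_op <- function(class_id) {
  switch(((class_id - 1) %% 4) + 1,
         rotation_matrix(c(0, 0, 1), 180),  # face-to-face, up-up
         diag(3),                           # face-to-back, up-up
         rotation_matrix(c(0, 1, 0), 180),  # face-to-face, up-down
         rotation_matrix(c(1, 0, 0), 180))  # face-to-back, up-down
}

#' Build a steric-zipper fixture crystal
#'
#' Places two copies of an ideal sheet facing along x with the requested
#' closest approach and lateral offset, realizing the face pairing and
#' up/down orientation of the requested topology class, inside a P1 cell
#' whose lattice repeats reproduce the periodic packing (sheets continue
#' through the cell along the sheet axis).
#'
#' @param spec a [zipper_spec()].
#' @return a `crystal_model` containing one repeating unit of each sheet,
#'   with a `groundtruth` attribute.
#' @export
build_zipper <- function(spec) {
  ss <- spec$sheet_spec
  unit_size <- if (ss$arrangement == "parallel") 1L else 2L
  # cell content: one repeating unit per sheet; the lattice continues the sheet
  uspec <- ss; uspec$n_strands <- unit_size
  built <- build_sheet_chains(uspec, LETTERS[seq_len(unit_size)])
  A <- do.call(rbind, built$chains)
  Rop <- .class_op(spec$class_id)
  B <- rotate_atoms(A, Rop)
  nb <- length(LETTERS)
  B$chain <- LETTERS[match(B$chain, LETTERS) + unit_size]

  # push B along +x until the closest approach equals the requested gap
  target <- spec$inter_sheet_gap
  place_b <- function(B0, zoff) {
    B0 <- translate_atoms(B0, c(max(A$x) - min(B0$x), 0, zoff))
    lo <- 0; hi <- 40
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      d <- cpp_min_dist(coords_of(A), coords_of(translate_atoms(B0, c(mid, 0, 0))), 0)
      if (d < target) lo <- mid else hi <- mid
    }
    translate_atoms(B0, c(hi, 0, 0))
  }
  if (is.null(spec$lateral_offset)) {
    # deterministic interdigitation scan: the (y, z) offset of sheet B that
    # maximizes the buried contact area at the requested closest approach
    # (side chains slotting between the partner's strand rows and ladders).
    # Burial is scored as the negative union SASA, since the isolated-sheet
    # areas do not depend on the offset.
    sph <- fibonacci_sphere(240)
    nres <- nchar(ss$sequence)
    pack_score <- function(Bz) {
      # buried contact area scored on interior residues only, so that
      # matched fixtures of different chain lengths pack identically;
      # placements that slipped through an open channel (closest approach
      # below the target) are rejected
      if (cpp_min_dist(coords_of(A), coords_of(Bz), 0) < target - 0.1)
        return(-Inf)
      u <- rbind(A, Bz)
      per <- cpp_sasa(coords_of(u), u$radius, 1.4, sph)
      -sum(per[u$resno > 1 & u$resno < nres])
    }
    # antiparallel pairs keep the strand rows near-aligned (offsets up to a
    # quarter spacing) so the up/down orientation of facing strands stays
    # well defined; parallel pairs may interleave up to half a spacing
    ymax <- ss$strand_spacing / (if (ss$arrangement == "parallel") 2 else 4)
    offs <- expand.grid(y = seq(0, ymax, by = ss$strand_spacing / 8),
                        z = seq(-6.8, 6.8, by = 0.4))
    score <- vapply(seq_len(nrow(offs)), function(i) {
      pack_score(place_b(translate_atoms(B, c(0, offs$y[i], 0)), offs$z[i]))
    }, numeric(1))
    best <- which.max(score)
    yb <- offs$y[best]; zb <- offs$z[best]
    fine <- expand.grid(y = yb + seq(-0.3, 0.3, by = 0.15),
                        z = zb + seq(-0.3, 0.3, by = 0.1))
    fs <- vapply(seq_len(nrow(fine)), function(i) {
      pack_score(place_b(translate_atoms(B, c(0, fine$y[i], 0)), fine$z[i]))
    }, numeric(1))
    best <- which.max(fs)
    zoff_used <- c(fine$y[best], fine$z[best])
    B <- place_b(translate_atoms(B, c(0, zoff_used[1], 0)), zoff_used[2])
  } else if (length(spec$lateral_offset) == 2) {
    zoff_used <- as.numeric(spec$lateral_offset)
    B <- place_b(translate_atoms(B, c(0, zoff_used[1], 0)), zoff_used[2])
  } else {
    zoff_used <- c(0, spec$lateral_offset)
    B <- place_b(B, spec$lateral_offset)
  }

  atoms <- rbind(A, B)
  rownames(atoms) <- NULL
  xyz <- coords_of(atoms)

  # lattice vectors in the construction frame; for the periodic catemer the
  # x-repeat is chosen so the second (inter-sandwich) interface also packs
  # at the requested closest approach, with its own interdigitation scan
  wx <- diff(range(atoms$x))
  zext <- diff(range(atoms$z))
  period_y <- built$period
  solve_va <- function(dy, dz) {
    xb <- coords_of(B)
    lo <- 0; hi <- wx + 40
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      d <- cpp_min_dist(xb, sweep(coords_of(A), 2, -c(mid, dy, dz)), 0)
      if (d < target) lo <- mid else hi <- mid
    }
    c(hi, dy, dz)
  }
  va <- switch(spec$network,
    "2D" = {
      sph <- fibonacci_sphere(240)
      xb <- coords_of(B)
      nres <- nchar(ss$sequence)
      sc_score <- function(v) {
        u <- rbind(B, A)
        xu <- rbind(xb, sweep(coords_of(A), 2, -v))
        per <- cpp_sasa(xu, u$radius, 1.4, sph)
        -sum(per[u$resno > 1 & u$resno < nres])
      }
      ymax2 <- ss$strand_spacing / (if (ss$arrangement == "parallel") 2 else 4)
      offs <- expand.grid(y = seq(0, ymax2, by = ss$strand_spacing / 8),
                          z = seq(-6.8, 6.8, by = 0.4))
      sc <- vapply(seq_len(nrow(offs)), function(i) {
        sc_score(solve_va(offs$y[i], offs$z[i]))
      }, numeric(1))
      best <- which.max(sc)
      solve_va(offs$y[best], offs$z[best])
    },
    "1D" = c(wx + 30, 0, 0),
    # brick shear: half the z-repeat, centred so the two staggered partners
    # across the sheared step bury symmetrically, with the same
    # interdigitation scan as the catemer so the staggered faces mesh
    # rather than arrest on a corner contact
    "3D" = {
      sph <- fibonacci_sphere(240)
      xb <- coords_of(B)
      nres3 <- nchar(ss$sequence)
      half <- zoff_used[2] + (zext + 2) / 2
      vc3 <- c(0, 0, zext + 2)
      # score the worse of the two staggered contacts (A+va vs B and
      # A+va-vc vs B) so both halves of the brick bury comparably
      sc_score <- function(v) {
        one <- function(shift) {
          xa2 <- sweep(coords_of(A), 2, -(v - shift))
          if (cpp_min_dist(xb, xa2, 0) < target - 0.1) return(-Inf)
          u <- rbind(B, A)
          per <- cpp_sasa(rbind(xb, xa2), u$radius, 1.4, sph)
          -sum(per[u$resno > 1 & u$resno < nres3])
        }
        min(one(c(0, 0, 0)), one(vc3))
      }
      offs <- expand.grid(y = seq(0, ss$strand_spacing / 2,
                                  by = ss$strand_spacing / 8),
                          z = half + seq(-3.5, 3.5, by = 0.5))
      sc <- vapply(seq_len(nrow(offs)), function(i) {
        sc_score(solve_va(offs$y[i], offs$z[i]))
      }, numeric(1))
      best <- which.max(sc)
      solve_va(offs$y[best], offs$z[best])
    })
  vb <- period_y
  vc <- if (spec$network == "3D") c(0, 0, zext + 2) else c(0, 0, zext + 40)
  L <- cbind(va, vb, vc)

  # rotate model + lattice into the CRYST1 orthogonalization convention
  e1 <- unitv(va)
  e3 <- unitv(vcross(va, vb))
  e2 <- vcross(e3, e1)
  U <- rbind(e1, e2, e3)
  xyz <- xyz %*% t(U)
  Lr <- U %*% L
  atoms <- set_coords(atoms, xyz)

  cl <- function(v) vnorm(v)
  cang <- function(u, v) acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) / DEG
  cell <- c(cl(Lr[, 1]), cl(Lr[, 2]), cl(Lr[, 3]),
            cang(Lr[, 2], Lr[, 3]), cang(Lr[, 1], Lr[, 3]), cang(Lr[, 1], Lr[, 2]))
  m <- crystal_model(atoms, cell, "P 1")
  attr(m, "groundtruth") <- list(
    kind = "zipper", class_id = spec$class_id,
    packing_offset = zoff_used,
    arrangement = ss$arrangement, unit_size = unit_size,
    sheet_chains = list(a = unique(A$chain), b = unique(B$chain)),
    axis_y = as.numeric(U %*% unitv(vb)),
    axis_x = as.numeric(U %*% c(1, 0, 0)),
    network = spec$network, spec = spec)
  m
}

#' Add a solvent molecule to a model
#'
#' Places a single water oxygen at the given position (used to build
#' partially wet interface fixtures).
#'
#' @param model a `crystal_model`.
#' @param position 3-vector, angstrom.
#' @return the model with one HOH oxygen appended.
#' @export
add_water <- function(model, position) {
  w <- new_atoms("O", "O", "HOH", max(model$atoms$resno) + 1L, "W",
                 matrix(position, 1, 3), het = TRUE)
  w$peptide <- FALSE
  model$atoms <- rbind(model$atoms, w)
  model$atoms$serial <- seq_len(nrow(model$atoms))
  model
}
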