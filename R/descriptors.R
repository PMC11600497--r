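# Interface descriptors on a standardized slab of a beta-sheet pair:
# buried area Ab, shape complementarity Sc, and the Surface Detail Index
# SDi with its footprint rectangle.
#
# The slab holds 3 repeating units of each sheet (3 chains parallel,
# 2 chain pairs = 6 chains antiparallel); Ab is evaluated on the middle
# repeating unit only, so that edge effects and intra-sheet burial cancel:
#   Ab = (SASA_A + SASA_B - SASA_U) / N,   N = 2 (parallel), 4 (antiparallel)

#' Select the standardized analysis slab of a contacting sheet pair
#'
#' Takes the central three repeating units of each sheet (one strand per
#' unit for parallel, one strand pair for antiparallel sheets), centered on
#' the closest-approach region of the pair.
#'
#' @param sheet_a,sheet_b `beta_sheet` objects in contact.
#' @param lattice the `expanded_lattice` containing them.
#' @return an `analysis_slab`.
#' @export
select_slab <- function(sheet_a, sheet_b, lattice) {
  lattice <- as_lattice(lattice)
  a <- lattice$atoms[lattice$atoms$peptide, , drop = FALSE]
  # closest-approach point of the pair: both windows are centered on it so
  # the two 3-unit slabs face each other
  xa <- coords_of(a[a$copy %in% sheet_a$copies, , drop = FALSE])
  xb <- coords_of(a[a$copy %in% sheet_b$copies, , drop = FALSE])
  nn <- cpp_nn(xa, xb)
  i <- which.min(nn$dist)
  contact <- (xa[i, ] + xb[nn$idx[i], ]) / 2
  windows <- function(sheet) {
    u <- sheet$unit_size
    n <- length(sheet$copies)
    if (n < 3 * u) stop("insufficient lattice expansion: sheet has ", n,
                        " strands, need ", 3 * u)
    lapply(seq(1, n - 3 * u + 1), function(s) {
      midc <- sheet$copies[(s + u):(s + 2 * u - 1)]
      mc <- colMeans(coords_of(a[a$copy %in% midc, , drop = FALSE]))
      list(chains = sheet$copies[s:(s + 3 * u - 1)], mid = midc,
           y = sum(mc * sheet_a$axis_y),
           d = abs(sum((mc - contact) * sheet_a$axis_y)))
    })
  }
  # choose the two 3-unit windows jointly: facing each other (smallest
  # mid-unit offset along the sheet axis), nearest the contact region
  wa <- windows(sheet_a); wb <- windows(sheet_b)
  best <- NULL; best_score <- Inf
  for (i in seq_along(wa)) for (j in seq_along(wb)) {
    score <- abs(wa[[i]]$y - wb[[j]]$y) + 0.1 * (wa[[i]]$d + wb[[j]]$d)
    if (score < best_score) { best_score <- score; best <- c(i, j) }
  }
  pa <- wa[[best[1]]]
  pb <- wb[[best[2]]]
  stopifnot(sheet_a$unit_size == sheet_b$unit_size)
  u <- sheet_a$unit_size
  structure(list(
    a_chains = pa$chains, b_chains = pb$chains,
    a_mid = pa$mid, b_mid = pb$mid,
    unit_size = u, N = 2L * u,
    arrangement = sheet_a$arrangement,
    axis_y = sheet_a$axis_y,
    spacing = sheet_a$mean_strand_spacing,
    sheet_a = sheet_a, sheet_b = sheet_b,
    atoms = a[a$copy %in% c(pa$chains, pb$chains), , drop = FALSE]),
    class = "analysis_slab")
}

slab_atoms <- function(slab, which) {
  a <- slab$atoms
  ids <- switch(which, a = slab$a_chains, b = slab$b_chains,
                a_mid = slab$a_mid, b_mid = slab$b_mid,
                u = c(slab$a_chains, slab$b_chains))
  a[a$copy %in% ids, , drop = FALSE]
}

#' Solvent-accessible surface area
#'
#' Rolling-probe SASA by deterministic high-density sphere sampling
#' (spherical Fibonacci point set; no randomness), with per-atom
#' decomposition.
#'
#' @param atoms atom table with radii.
#' @param probe_radius probe radius, angstrom (water: 1.4).
#' @param n_dots sample points per atom (>= 960 for ~1 percent accuracy).
#' @return a `sasa_result`: list(per_atom, total, probe_radius).
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_dots = 960) {
  if (!nrow(atoms)) stop("no atoms for SASA computation")
  per <- cpp_sasa(coords_of(atoms), atoms$radius, probe_radius,
                  fibonacci_sphere(n_dots))
  structure(list(per_atom = per, total = sum(per),
                 probe_radius = probe_radius),
            class = "sasa_result")
}

#' Per-chain buried area of a zipper interface (Ab)
#'
#' SASA of the middle repeating unit of each sheet, computed in the context
#' of its own 3-unit slab with the partner absent (SASA_A, SASA_B) and with
#' both slabs present (SASA_U); the per-chain buried area is
#' (SASA_A + SASA_B - SASA_U) / N with N = 2 (parallel) or 4 (antiparallel).
#'
#' @param slab an `analysis_slab`.
#' @param probe_radius angstrom.
#' @param n_dots SASA sampling density.
#' @param details if TRUE return the SASA components as well.
#' @return Ab in square angstrom per peptide chain (or a list if `details`).
#' @export
buried_area <- function(slab, probe_radius = 1.4, n_dots = 960,
                        details = FALSE) {
  mid_sum <- function(ctx, mid_ids) {
    per <- cpp_sasa(coords_of(ctx), ctx$radius, probe_radius,
                    fibonacci_sphere(n_dots))
    sum(per[ctx$copy %in% mid_ids])
  }
  A <- slab_atoms(slab, "a"); B <- slab_atoms(slab, "b")
  U <- rbind(A, B)
  sasa_a <- mid_sum(A, slab$a_mid)
  sasa_b <- mid_sum(B, slab$b_mid)
  sasa_u <- mid_sum(U, c(slab$a_mid, slab$b_mid))
  ab <- (sasa_a + sasa_b - sasa_u) / slab$N
  if (ab < -1) stop("negative buried area: inconsistent slab geometry")
  ab <- max(ab, 0)
  if (details) list(Ab = ab, SASA_A = sasa_a, SASA_B = sasa_b,
                    SASA_U = sasa_u, N = slab$N) else ab
}

# Per-residue side-chain burial between the two slabs: SASA of each chain's
# side-chain atoms (CA for glycine) alone vs with the partner slab present.
# Used by the interface admission criteria.
residue_burial <- function(slab, probe_radius = 1.4, n_dots = 480) {
  A <- slab_atoms(slab, "a"); B <- slab_atoms(slab, "b")
  per_side <- function(own, partner) {
    ctx0 <- own; ctx1 <- rbind(own, partner)
    s0 <- cpp_sasa(coords_of(ctx0), ctx0$radius, probe_radius,
                   fibonacci_sphere(n_dots))
    s1 <- cpp_sasa(coords_of(ctx1), ctx1$radius, probe_radius,
                   fibonacci_sphere(n_dots))[seq_len(nrow(own))]
    bur <- s0 - s1
    sc <- (own$name %in% c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2",
                           "CE", "CE1", "CE2", "CE3", "CZ", "CZ2", "CZ3",
                           "CH2", "ND1", "ND2", "NE", "NE1", "NE2", "NH1",
                           "NH2", "NZ", "OD1", "OD2", "OE1", "OE2", "OG",
                           "OG1", "OH", "SD", "SG")) |
      (own$resname == "GLY" & own$name == "CA")
    agg <- stats::aggregate(bur[sc],
                            by = list(copy = own$copy[sc],
                                      resno = own$resno[sc],
                                      resname = own$resname[sc]), FUN = sum)
    names(agg)[4] <- "side_chain_burial"
    agg
  }
  rbind(cbind(sheet = "a", per_side(A, B)),
        cbind(sheet = "b", per_side(B, A)))
}

#' Shape complementarity (Sc) of a zipper interface
#'
#' Molecular contact surfaces of the two slabs are sampled as accessible
#' dots on the van der Waals spheres; the buried portions are the points
#' within `cutoff` of the partner surface. Each buried point is paired with
#' its nearest partner point and scored by the opposed-normal agreement
#' weighted with exp(-w d^2); Sc is the median over both directions pooled
#' (Lawrence-Colman convention).
#'
#' @param slab an `analysis_slab`.
#' @param probe_radius angstrom.
#' @param cutoff buried-surface distance cutoff, angstrom.
#' @param w distance weight, 1/angstrom^2.
#' @param n_dots surface sampling per atom.
#' @return Sc in [-1, 1].
#' @export
shape_complementarity <- function(slab, probe_radius = 1.4, cutoff = 1.0,
                                  w = 0.5, n_dots = 720) {
  A <- slab_atoms(slab, "a"); B <- slab_atoms(slab, "b")
  sph <- fibonacci_sphere(n_dots)
  # restrict to atoms near the interface before sampling
  xa <- coords_of(A); xb <- coords_of(B)
  nnab <- cpp_nn(xa, xb)
  near_a <- nnab$dist < 2 * max(A$radius) + 2 * probe_radius + cutoff + 1
  nnba <- cpp_nn(xb, xa)
  near_b <- nnba$dist < 2 * max(B$radius) + 2 * probe_radius + cutoff + 1
  dots_a <- cpp_surface_dots(xa, A$radius, probe_radius, sph)
  dots_b <- cpp_surface_dots(xb, B$radius, probe_radius, sph)
  keep_a <- near_a[dots_a$atom]
  keep_b <- near_b[dots_b$atom]
  Pa <- dots_a$points[keep_a, , drop = FALSE]
  Na <- dots_a$normals[keep_a, , drop = FALSE]
  Pb <- dots_b$points[keep_b, , drop = FALSE]
  Nb <- dots_b$normals[keep_b, , drop = FALSE]
  if (!nrow(Pa) || !nrow(Pb)) stop("no interface: empty buried surface")
  sc_dir <- function(P1, N1, P2, N2) {
    nn <- cpp_nn(P1, P2)
    buried <- nn$dist <= cutoff
    if (!any(buried)) return(numeric(0))
    i <- which(buried)
    j <- nn$idx[i]
    s <- -rowSums(N1[i, , drop = FALSE] * N2[j, , drop = FALSE])
    s * exp(-w * nn$dist[i]^2)
  }
  s <- c(sc_dir(Pa, Na, Pb, Nb), sc_dir(Pb, Nb, Pa, Na))
  if (!length(s)) stop("no interface: empty buried surface")
  stats::median(s)
}

#' Footprint rectangle of a zipper interface
#'
#' Width: repeating-unit extent along the sheet axis (mean inter-strand
#' centroid spacing times strands per repeating unit). Length: in the
#' projection along the sheet axis, atoms become disks of van der Waals
#' radius; a probe disk (1.4 angstrom) approaches the groove between the
#' two sheet profiles from both open ends, and at each end the position
#' simultaneously tangent to both profiles defines the endpoint as the
#' innermost facing point of the probe circle.
#'
#' @param slab an `analysis_slab`.
#' @param probe_radius angstrom.
#' @return list(length, width, endpoints) in angstrom.
#' @export
footprint_rectangle <- function(slab, probe_radius = 1.4) {
  A <- slab_atoms(slab, "a"); B <- slab_atoms(slab, "b")
  y <- unitv(slab$axis_y)
  ctr_a <- colMeans(coords_of(A)); ctr_b <- colMeans(coords_of(B))
  xdir <- ctr_b - ctr_a
  xdir <- unitv(xdir - sum(xdir * y) * y)
  zdir <- vcross(xdir, y)
  proj <- function(at) {
    xyz <- sweep(coords_of(at), 2, (ctr_a + ctr_b) / 2)
    cbind(x = xyz %*% xdir, z = xyz %*% zdir, r = at$radius)
  }
  da <- proj(A); db <- proj(B)

  gdist <- function(p, d) min(sqrt((d[, 1] - p[1])^2 + (d[, 2] - p[2])^2) - d[, 3]) -
    probe_radius
  # best clearance of a probe at height z: maximum over the groove (probe
  # centres between the two sheets' centre planes) of the distance to the
  # nearer profile; the probe fits at z iff this is non-negative
  xlo <- mean(da[, 1]); xhi <- mean(db[, 1])
  clear_xz <- function(xv, z, d) {
    m <- sqrt(outer(xv, d[, 1], `-`)^2 +
                matrix((d[, 2] - z)^2, length(xv), nrow(d), byrow = TRUE))
    m <- sweep(m, 2, d[, 3])
    apply(m, 1, min) - probe_radius
  }
  balance <- function(z) {
    xv <- seq(xlo, xhi, by = 0.1)
    h <- pmin(clear_xz(xv, z, da), clear_xz(xv, z, db))
    i <- which.max(h)
    xf <- seq(xv[i] - 0.1, xv[i] + 0.1, by = 0.02)
    hf <- pmin(clear_xz(xf, z, da), clear_xz(xf, z, db))
    j <- which.max(hf)
    list(x = xf[j], h = hf[j])
  }
  zr <- range(c(da[, 2], db[, 2]))
  zmid <- mean(zr)
  if (balance(zmid)$h > 0)
    stop("no closed interface: probe passes between the sheets")
  endpoint <- function(direction) {
    # roll the probe in from the open end: the first position where it
    # wedges (clearance drops to zero) is the tangency
    zfar <- zmid + direction * (diff(zr) / 2 + 4 * probe_radius + 2)
    zs <- seq(zfar, zmid, by = -direction * 0.1)
    hprev <- balance(zs[1])$h
    zcross <- NA
    for (k in 2:length(zs)) {
      h <- balance(zs[k])$h
      if (hprev > 0 && h <= 0) { zcross <- c(zs[k], zs[k - 1]); break }
      hprev <- h
    }
    if (anyNA(zcross) || is.na(zcross[1]))
      stop("no closed interface: probe tangency not found")
    for (it in 1:40) {
      zm <- mean(zcross)
      if (balance(zm)$h <= 0) zcross[1] <- zm else zcross[2] <- zm
    }
    zt <- mean(zcross)
    b <- balance(zt)
    p <- c(b$x, zt)
    touch <- function(d) {
      dd <- sqrt((d[, 1] - p[1])^2 + (d[, 2] - p[2])^2) - d[, 3]
      d[which.min(dd), 1:2]
    }
    ca <- touch(da); cb <- touch(db)
    u <- unitv(unitv(ca - p) + unitv(cb - p))
    if (sign(u[2]) != sign(zmid - zt)) u <- -u   # point into the groove
    p + probe_radius * u
  }
  e1 <- endpoint(-1); e2 <- endpoint(1)
  len <- vnorm(e2 - e1)
  width <- slab$spacing * slab$unit_size
  list(length = len, width = width,
       endpoints = rbind(e1, e2))
}

#' Surface Detail Index (SDi)
#'
#' Ratio of the one-sided buried area of one repeating unit of the
#' interface (Ab times the chains per repeating unit) to the area of its
#' flat rectangular footprint. About 1 for flat interfaces, rising towards
#' 1.8-1.9 for strongly interdigitated, cog-like zippers.
#'
#' @param slab an `analysis_slab`.
#' @param Ab optional precomputed buried area (recomputed if NULL).
#' @param footprint optional precomputed [footprint_rectangle()] result.
#' @param probe_radius angstrom.
#' @return SDi (dimensionless).
#' @export
surface_detail_index <- function(slab, Ab = NULL, footprint = NULL,
                                 probe_radius = 1.4) {
  if (is.null(Ab)) Ab <- buried_area(slab, probe_radius)
  if (is.null(footprint)) footprint <- footprint_rectangle(slab, probe_radius)
  area <- footprint$length * footprint$width
  if (area <= 0) stop("zero-area footprint")
  (Ab * slab$unit_size) / area
}

#' All three descriptors of one interface
#'
#' @param slab an `analysis_slab`.
#' @param probe_radius angstrom.
#' @return a `descriptor_set`: list(Sc, Ab, SDi, footprint, N).
#' @export
descriptor_set <- function(slab, probe_radius = 1.4) {
  ab <- buried_area(slab, probe_radius)
  fp <- footprint_rectangle(slab, probe_radius)
  structure(list(
    Sc = shape_complementarity(slab, probe_radius),
    Ab = ab,
    SDi = surface_detail_index(slab, Ab = ab, footprint = fp),
    footprint = c(length = fp$length, width = fp$width),
    N = slab$N),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("Sc %.2f | Ab %.1f A^2/chain | SDi %.2f | footprint %.1f x %.1f A\n",
              x$Sc, x$Ab, x$SDi, x$footprint["length"], x$footprint["width"]))
  invisible(x)
}
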