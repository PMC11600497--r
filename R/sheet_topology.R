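# Backbone H-bond detection, beta-sheet assembly, facial composition and
# topology class assignment (classes 1-8 with out-of-register and LARKS
# auxiliary flags).

#' Detect inter-backbone H-bonds in an expanded lattice
#'
#' Finds all N(H)...O=C pairs between distinct chain copies with N...O
#' distance at most `d_max` and C=O...N angle at least `angle_min`. Hydrogen
#' positions are not required (models are analyzed without hydrogens).
#'
#' @param lattice an `expanded_lattice` (or a `crystal_model`, whose chains
#'   are then treated as the copies).
#' @param d_max N...O distance cutoff, angstrom.
#' @param angle_min C=O...N angle cutoff, degrees.
#' @return data.frame with one row per H-bond: donor/acceptor copy, residue,
#'   distance and angle.
#' @export
detect_backbone_hbonds <- function(lattice, d_max = 3.5, angle_min = 120) {
  lattice <- as_lattice(lattice)
  a <- lattice$atoms[lattice$atoms$peptide, , drop = FALSE]
  copies <- unique(a$copy)
  # bounding-sphere prefilter per copy pair
  ctr <- t(vapply(copies, function(k) colMeans(coords_of(a[a$copy == k, ])),
                  numeric(3)))
  rad <- vapply(seq_along(copies), function(i) {
    x <- coords_of(a[a$copy == copies[i], ])
    sqrt(max(rowSums(sweep(x, 2, ctr[i, ])^2)))
  }, numeric(1))
  out <- list()
  for (i in seq_along(copies)) {
    ai <- a[a$copy == copies[i], , drop = FALSE]
    for (j in seq_along(copies)) {
      if (i == j) next
      if (vnorm(ctr[i, ] - ctr[j, ]) > rad[i] + rad[j] + d_max) next
      aj <- a[a$copy == copies[j], , drop = FALSE]
      h <- hbond_pairs(ai, aj, d_max = d_max, angle_min = angle_min)
      if (!is.null(h)) {
        h$don_copy <- copies[i]; h$acc_copy <- copies[j]
        out[[length(out) + 1]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(don_res = integer(), acc_res = integer(),
                      distance = numeric(), angle = numeric(),
                      don_copy = integer(), acc_copy = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# H-bond count of one chain copy (donated + accepted).
hbond_count <- function(hbonds, copy) {
  sum(hbonds$don_copy == copy) + sum(hbonds$acc_copy == copy)
}

strand_direction <- function(atoms) {
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), ]
  unitv(c(ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1],
          ca$z[nrow(ca)] - ca$z[1]))
}

# Side-chain direction of each residue of one strand: CB-CA, with a
# pseudo-CB (negative bisector of N-CA and C-CA) for glycine.
residue_side_vectors <- function(atoms) {
  res <- sort(unique(atoms$resno))
  t(vapply(res, function(r) {
    g <- function(nm) {
      i <- which(atoms$resno == r & atoms$name == nm)[1]
      if (is.na(i)) return(NULL)
      c(atoms$x[i], atoms$y[i], atoms$z[i])
    }
    ca <- g("CA"); cb <- g("CB")
    if (!is.null(cb)) return(unitv(cb - ca))
    nn <- g("N"); cc <- g("C")
    unitv(-(unitv(nn - ca) + unitv(cc - ca)))
  }, numeric(3)))
}

#' Assemble beta-sheets from chain copies and H-bonds
#'
#' Strand pairs sharing at least `min_hbonds` H-bonds become neighbours; the
#' connected components of that graph are the sheets, with strands ordered
#' along the stacking (sheet) axis.
#'
#' @param lattice an `expanded_lattice` (or `crystal_model`).
#' @param hbonds output of [detect_backbone_hbonds()].
#' @param min_hbonds minimum H-bonds between neighbouring strands.
#' @return list of `beta_sheet` objects.
#' @export
assemble_sheets <- function(lattice, hbonds, min_hbonds = 2) {
  lattice <- as_lattice(lattice)
  a <- lattice$atoms[lattice$atoms$peptide, , drop = FALSE]
  if (!nrow(hbonds)) return(list())
  pk <- paste(pmin(hbonds$don_copy, hbonds$acc_copy),
              pmax(hbonds$don_copy, hbonds$acc_copy))
  tab <- table(pk)
  good <- names(tab)[tab >= min_hbonds]
  if (!length(good)) return(list())
  ed <- do.call(rbind, strsplit(good, " "))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  sheets <- list()
  for (ci in seq_len(comp$no)) {
    copies <- as.integer(igraph::V(g)$name[comp$membership == ci])
    if (length(copies) < 2) next
    satoms <- a[a$copy %in% copies, , drop = FALSE]
    ctr <- t(vapply(copies, function(k)
      colMeans(coords_of(satoms[satoms$copy == k, ])), numeric(3)))
    dirs <- lapply(copies, function(k)
      strand_direction(satoms[satoms$copy == k, ]))
    # stacking axis: principal direction of the strand centroids
    cc <- sweep(ctr, 2, colMeans(ctr))
    axis_y <- svd(cc)$v[, 1]
    ord <- order(ctr %*% axis_y)
    copies <- copies[ord]; ctr <- ctr[ord, , drop = FALSE]; dirs <- dirs[ord]
    # canonical sign: axis_y points from the first to the last strand
    axis_y <- unitv(ctr[nrow(ctr), ] - ctr[1, ])
    ndots <- vapply(seq_along(dirs)[-1],
                    function(i) sum(dirs[[i]] * dirs[[i - 1]]), numeric(1))
    arrangement <- if (all(ndots > 0)) "parallel" else "antiparallel"
    sdir <- dirs[[1]]
    axis_x <- unitv(vcross(axis_y, sdir))
    spacing <- mean(diff(ctr %*% axis_y))

    # facial composition: side-chain orientation about the sheet plane
    fp <- list(); fn <- list()
    for (k in seq_along(copies)) {
      sa <- satoms[satoms$copy == copies[k], , drop = FALSE]
      sv <- residue_side_vectors(sa)
      res <- sort(unique(sa$resno))
      s <- sv %*% axis_x
      rn <- vapply(res, function(r) sa$resname[sa$resno == r][1], character(1))
      fp[[k]] <- data.frame(copy = copies[k], resno = res[s > 0],
                            resname = rn[s > 0])
      fn[[k]] <- data.frame(copy = copies[k], resno = res[s <= 0],
                            resname = rn[s <= 0])
    }
    face_pos <- do.call(rbind, fp); face_neg <- do.call(rbind, fn)
    equi <- identical(sort(as.character(face_pos$resname)),
                      sort(as.character(face_neg$resname)))
    sheets[[length(sheets) + 1]] <- structure(list(
      copies = copies, centroids = ctr, directions = dirs,
      arrangement = arrangement, axis_y = as.numeric(axis_y),
      axis_x = as.numeric(axis_x), strand_dir = as.numeric(sdir),
      mean_strand_spacing = spacing,
      face_pos = face_pos, face_neg = face_neg,
      facial_type = if (equi) "equifacial" else "antifacial",
      unit_size = if (arrangement == "parallel") 1L else 2L,
      n_residues = length(unique(satoms$resno))),
      class = "beta_sheet")
  }
  sheets
}

#' @export
print.beta_sheet <- function(x, ...) {
  cat("beta_sheet:", length(x$copies), "strands,", x$arrangement, ",",
      x$facial_type, sprintf(", spacing %.2f A\n", x$mean_strand_spacing))
  invisible(x)
}

#' Facial composition of a beta-sheet
#'
#' Reports the two face residue sets, whether the sheet is equifacial
#' (identical residue-type multisets on both faces) or antifacial, and the
#' residue-position parity of each face.
#'
#' @param sheet a `beta_sheet`.
#' @return list with `facial_type`, `face_pos`, `face_neg` and the sorted
#'   unique residue positions per face.
#' @export
facial_analysis <- function(sheet) {
  list(facial_type = sheet$facial_type,
       face_pos = sheet$face_pos, face_neg = sheet$face_neg,
       positions_pos = sort(unique(sheet$face_pos$resno)),
       positions_neg = sort(unique(sheet$face_neg$resno)))
}

# Which residue positions of `sheet` present side chains toward a partner
# lying in direction `toward` (unit vector from this sheet to the partner).
contact_face <- function(sheet, toward) {
  if (sum(sheet$axis_x * toward) > 0) {
    list(side = "pos", positions = sort(unique(sheet$face_pos$resno)),
         residues = sheet$face_pos)
  } else {
    list(side = "neg", positions = sort(unique(sheet$face_neg$resno)),
         residues = sheet$face_neg)
  }
}

#' Out-of-register detection
#'
#' Compares the modal H-bond registry offset of neighbouring strands with
#' the in-register value; reports the shift (in residues, as a magnitude)
#' and the angle between the strand direction and the sheet axis.
#'
#' @param sheet a `beta_sheet`.
#' @param hbonds the lattice H-bond table.
#' @return list(oor = flag, shift = integer, tilt = degrees from
#'   perpendicular).
#' @export
detect_out_of_register <- function(sheet, hbonds) {
  cp <- sheet$copies
  L <- sheet$n_residues
  offs <- numeric(0)
  for (k in seq_len(length(cp) - 1)) {
    lo <- cp[k]; hi <- cp[k + 1]
    h <- hbonds[(hbonds$don_copy == lo & hbonds$acc_copy == hi) |
                  (hbonds$don_copy == hi & hbonds$acc_copy == lo), , drop = FALSE]
    if (!nrow(h)) next
    hi_res <- ifelse(h$don_copy == hi, h$don_res, h$acc_res)
    lo_res <- ifelse(h$don_copy == hi, h$acc_res, h$don_res)
    same_dir <- sum(sheet$directions[[k]] * sheet$directions[[k + 1]]) > 0
    o <- if (same_dir) hi_res - lo_res else hi_res + lo_res - (L + 1)
    offs <- c(offs, mean(o))
  }
  shift <- if (length(offs)) as.integer(round(mean(offs))) else 0L
  tilt <- abs(90 - acos(abs(sum(sheet$strand_dir * sheet$axis_y))) / DEG)
  list(oor = shift != 0L, shift = abs(shift), tilt = tilt)
}

#' LARKS (kinked-backbone) detection for one chain
#'
#' Flags a chain when at least one interior residue lies farther than
#' `margin` degrees (wrap-aware Euclidean distance in (phi, psi) space)
#' outside the allowed beta region.
#'
#' @param atoms atom table of one chain (>= 4 residues).
#' @param margin degrees.
#' @return logical flag.
#' @export
detect_larks <- function(atoms, margin = 30) {
  if (length(unique(atoms$resno)) < 4) stop("chain too short for LARKS analysis")
  d <- backbone_dihedrals(atoms)
  inter <- d[d$region != "unassigned-terminal", , drop = FALSE]
  any(beta_region_distance(inter$phi, inter$psi) > margin)
}

#' Assign the steric-zipper topology class of a contacting sheet pair
#'
#' Classes follow the standard combinatorics: (i) parallel (1-4) vs
#' antiparallel (5-8) sheets, (ii) whether the two sheets meet through the
#' same face or different faces, and (iii) the relative up/down orientation
#' of the facing strands. Out-of-register and kink flags are reported
#' alongside as a pseudoclass, never overriding the geometric class.
#'
#' @param sheet_a,sheet_b `beta_sheet` objects in contact.
#' @param lattice the `expanded_lattice` containing them.
#' @param hbonds lattice H-bond table (for the OoR flag).
#' @return a `topology_label`: list(class_id, arrangement, same_face,
#'   up_up, oor, shift, larks, pseudo, facial_type).
#' @export
assign_topology_class <- function(sheet_a, sheet_b, lattice, hbonds = NULL) {
  lattice <- as_lattice(lattice)
  if (sheet_a$arrangement != sheet_b$arrangement) {
    return(structure(list(class_id = NA_integer_,
                          diagnostic = "mixed parallel/antiparallel sheet pair"),
                     class = "topology_label"))
  }
  arrangement <- sheet_a$arrangement
  a <- lattice$atoms[lattice$atoms$peptide, ]
  ctr_a <- colMeans(coords_of(a[a$copy %in% sheet_a$copies, ]))
  ctr_b <- colMeans(coords_of(a[a$copy %in% sheet_b$copies, ]))
  w <- unitv(ctr_b - ctr_a)
  fa <- contact_face(sheet_a, w)
  fb <- contact_face(sheet_b, -w)
  same_face <- identical(fa$positions, fb$positions)
  # relative orientation of the facing strands, paired by position along
  # the (shared) sheet axis
  ya <- as.numeric(sheet_a$centroids %*% sheet_a$axis_y)
  yb <- as.numeric(sheet_b$centroids %*% sheet_a$axis_y)
  dots <- vapply(seq_along(sheet_a$copies), function(i) {
    j <- which.min(abs(yb - ya[i]))
    sum(sheet_a$directions[[i]] * sheet_b$directions[[j]])
  }, numeric(1))
  up_up <- mean(dots) > 0
  base <- if (same_face && up_up) 1L else if (!same_face && up_up) 2L
  else if (same_face) 3L else 4L
  class_id <- base + if (arrangement == "antiparallel") 4L else 0L
  oor <- list(oor = FALSE, shift = 0L)
  larks <- FALSE
  if (!is.null(hbonds)) {
    o1 <- detect_out_of_register(sheet_a, hbonds)
    o2 <- detect_out_of_register(sheet_b, hbonds)
    oor <- if (o1$oor || o2$oor) list(oor = TRUE, shift = max(o1$shift, o2$shift))
    else list(oor = FALSE, shift = 0L)
  }
  ch1 <- a[a$copy == sheet_a$copies[1], ]
  if (length(unique(ch1$resno)) >= 4) larks <- detect_larks(ch1)
  structure(list(class_id = class_id, arrangement = arrangement,
                 same_face = same_face, up_up = up_up,
                 face_a_positions = fa$positions,
                 face_b_positions = fb$positions,
                 oor = oor$oor, shift = oor$shift, larks = larks,
                 pseudo = oor$oor || larks,
                 facial_type = sheet_a$facial_type),
            class = "topology_label")
}

#' @export
print.topology_label <- function(x, ...) {
  if (is.na(x$class_id)) {
    cat("topology: unclassified (", x$diagnostic, ")\n")
  } else {
    cat("topology: class", x$class_id,
        if (x$pseudo) "(pseudoclass)" else "", x$arrangement,
        if (x$oor) sprintf("OoR shift %d", x$shift) else "",
        if (x$larks) "LARKS" else "", "\n")
  }
  invisible(x)
}
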