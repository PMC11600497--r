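# Enumeration and admission of steric-zipper interfaces: contacting
# beta-sheet pairs are admitted under four criteria, then deduplicated over
# symmetry-equivalent observations and tagged for trapped solvent.
#
# Admission criteria (defaults, all configurable):
#   (i)   per-chain buried area Ab >= 50 A^2
#   (ii)  every strand contributes at least one involved side chain
#   (iii) on average >= 1.5 involved side chains per peptide chain
#   (iv)  involvement = side-chain burial >= 10 A^2 (glycine: CA >= 5 A^2)

#' Find contacting beta-sheet pairs
#'
#' All unordered sheet pairs with at least one inter-atomic distance below
#' the sum of van der Waals radii plus two probe radii.
#'
#' @param sheets list of `beta_sheet` objects.
#' @param lattice the `expanded_lattice`.
#' @param probe_radius angstrom.
#' @return list of index pairs (i, j) into `sheets`.
#' @export
find_contacting_pairs <- function(sheets, lattice, probe_radius = 1.4) {
  lattice <- as_lattice(lattice)
  a <- lattice$atoms[lattice$atoms$peptide, , drop = FALSE]
  xyz <- lapply(sheets, function(s) coords_of(a[a$copy %in% s$copies, ]))
  rmax <- max(a$radius)
  out <- list()
  if (length(sheets) < 2) return(out)
  for (i in seq_len(length(sheets) - 1)) {
    for (j in (i + 1):length(sheets)) {
      lim <- 2 * rmax + 2 * probe_radius
      if (cpp_min_dist(xyz[[i]], xyz[[j]], 0) < lim)
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

#' Admit or reject a candidate zipper interface
#'
#' Evaluates the four admission criteria on the standardized slab of the
#' pair. Rejection reports the first failed criterion.
#'
#' @param sheet_a,sheet_b contacting `beta_sheet`s.
#' @param lattice the `expanded_lattice`.
#' @param hbonds lattice H-bond table (for the topology label).
#' @param min_buried_area criterion (i) threshold, A^2 per chain.
#' @param min_side_chain_burial criterion (iv) side-chain threshold, A^2.
#' @param min_gly_burial criterion (iv) glycine CA threshold, A^2.
#' @param min_mean_side_chains criterion (iii) threshold, side chains/chain.
#' @param probe_radius angstrom.
#' @param descriptors if TRUE compute Sc/Ab/SDi for admitted interfaces.
#' @return a `zipper_interface`, or a list(admitted = FALSE, reason, criterion).
#' @export
admit_interface <- function(sheet_a, sheet_b, lattice, hbonds = NULL,
                            min_buried_area = 50,
                            min_side_chain_burial = 10,
                            min_gly_burial = 5,
                            min_mean_side_chains = 1.5,
                            probe_radius = 1.4,
                            descriptors = TRUE) {
  lattice <- as_lattice(lattice)
  slab <- tryCatch(select_slab(sheet_a, sheet_b, lattice), error = function(e)
    NULL)
  if (is.null(slab)) {
    return(list(admitted = FALSE, criterion = NA_integer_,
                reason = "insufficient lattice expansion for a 3-unit slab"))
  }
  ab <- buried_area(slab, probe_radius)
  if (ab < min_buried_area) {
    return(list(admitted = FALSE, criterion = 1L,
                reason = sprintf("buried area %.1f A^2 below %.0f A^2",
                                 ab, min_buried_area)))
  }
  bur <- residue_burial(slab, probe_radius)
  thr <- ifelse(bur$resname == "GLY", min_gly_burial, min_side_chain_burial)
  bur$involved <- bur$side_chain_burial >= thr
  inv <- bur[bur$involved, , drop = FALSE]
  per_chain <- tapply(bur$involved, bur$copy, sum)
  if (any(per_chain == 0)) {
    return(list(admitted = FALSE, criterion = 2L,
                reason = "a strand contributes no involved side chain"))
  }
  mean_inv <- mean(per_chain)
  if (mean_inv < min_mean_side_chains) {
    return(list(admitted = FALSE, criterion = 3L,
                reason = sprintf("%.2f involved side chains per chain below %.1f",
                                 mean_inv, min_mean_side_chains)))
  }
  topo <- assign_topology_class(sheet_a, sheet_b, lattice, hbonds)
  # interface identity for symmetry deduplication: the contacting faces
  # (residue-position sets), which are stable across symmetry copies even
  # when single rim residues flicker around the involvement cutoff
  face_key <- paste(sort(c(paste(topo$face_a_positions, collapse = ","),
                           paste(topo$face_b_positions, collapse = ","))),
                    collapse = " : ")
  desc <- if (descriptors) {
    fp <- footprint_rectangle(slab, probe_radius)
    structure(list(Sc = shape_complementarity(slab, probe_radius),
                   Ab = ab,
                   SDi = surface_detail_index(slab, Ab = ab, footprint = fp),
                   footprint = c(length = fp$length, width = fp$width),
                   N = slab$N), class = "descriptor_set")
  } else NULL
  structure(list(
    admitted = TRUE, slab = slab, topology = topo,
    contacting = inv[, c("sheet", "copy", "resno", "resname",
                         "side_chain_burial")],
    residues_key = face_key,
    residues_label = interface_residue_label(inv),
    mean_involved = mean_inv,
    descriptors = desc, multiplicity = 1L),
    class = "zipper_interface")
}

# Canonical identity of an interface: the sorted residue sets on its two
# sides (orientation-independent), used for symmetry deduplication.
interface_residue_key <- function(inv) {
  side <- function(s) {
    r <- sort(unique(paste0(aa_one(inv$resname[inv$sheet == s]),
                            inv$resno[inv$sheet == s])))
    paste(r, collapse = " ")
  }
  paste(sort(c(side("a"), side("b"))), collapse = " : ")
}

interface_residue_label <- function(inv) {
  side <- function(s) {
    d <- inv[inv$sheet == s, c("resno", "resname")]
    d <- d[!duplicated(d$resno), , drop = FALSE]
    d <- d[order(d$resno), , drop = FALSE]
    paste0(aa_one(d$resname), d$resno, collapse = " ")
  }
  paste(side("a"), ":", side("b"))
}

#' @export
print.zipper_interface <- function(x, ...) {
  cat("zipper_interface:", x$residues_label, "\n  ")
  if (!is.null(x$topology) && !is.na(x$topology$class_id))
    cat("class", x$topology$class_id, "")
  if (!is.null(x$descriptors)) print(x$descriptors) else cat("\n")
  invisible(x)
}

#' Deduplicate symmetry-equivalent interfaces
#'
#' Groups observations by (interacting side-chain sets, topology class),
#' arithmetic-averages their descriptor values and records the
#' multiplicity. Idempotent and order-independent.
#'
#' @param interfaces list of admitted `zipper_interface`s.
#' @return list of unique `zipper_interface`s.
#' @export
deduplicate <- function(interfaces) {
  if (!length(interfaces)) return(interfaces)
  keys <- vapply(interfaces, function(i)
    paste(i$residues_key, "|", i$topology$class_id), character(1))
  out <- lapply(sort(unique(keys)), function(k) {
    grp <- interfaces[keys == k]
    base <- grp[[1]]
    base$multiplicity <- sum(vapply(grp, function(g)
      as.integer(g$multiplicity), integer(1)))
    if (!is.null(base$descriptors)) {
      for (f in c("Sc", "Ab", "SDi")) {
        base$descriptors[[f]] <- mean(vapply(grp, function(g)
          g$descriptors[[f]], numeric(1)))
      }
    }
    base
  })
  out
}

#' Classify interface wetness
#'
#' An interface is partially wet when at least one solvent molecule lies
#' between the two facing sheet surfaces: within the inter-sheet slab and
#' inside the footprint extent. Fully solvent-covered faces never pass the
#' admission criteria and so are not classified here.
#'
#' @param interface an admitted `zipper_interface`.
#' @param lattice the `expanded_lattice` (its solvent atoms are used).
#' @return "partially_wet" or "dry".
#' @export
classify_wetness <- function(interface, lattice) {
  lattice <- as_lattice(lattice)
  slab <- interface$slab
  sol <- lattice$atoms[!lattice$atoms$peptide &
                         lattice$atoms$resname %in%
                         c("HOH", "WAT", "DOD", "EOH", "ACN", "GOL", "EDO"),
                       , drop = FALSE]
  if (!nrow(sol)) return("dry")
  A <- slab_atoms(slab, "a"); B <- slab_atoms(slab, "b")
  y <- unitv(slab$axis_y)
  ctr_a <- colMeans(coords_of(A)); ctr_b <- colMeans(coords_of(B))
  xdir <- ctr_b - ctr_a; xdir <- unitv(xdir - sum(xdir * y) * y)
  zdir <- vcross(xdir, y)
  org <- (ctr_a + ctr_b) / 2
  frame <- function(at) {
    xyz <- sweep(coords_of(at), 2, org)
    cbind(xyz %*% xdir, xyz %*% y, xyz %*% zdir)
  }
  fa <- frame(A); fb <- frame(B); fs <- frame(sol)
  # facing surfaces: innermost atom planes of each sheet
  x_lo <- max(apply(fa, 1, function(r) r[1]))  # closest approach of A
  x_hi <- min(fb[, 1])
  if (x_lo > x_hi) { tmp <- x_lo; x_lo <- x_hi; x_hi <- tmp }
  yr <- range(c(fa[, 2], fb[, 2]))
  zr <- range(c(fa[, 3], fb[, 3]))
  inside <- fs[, 1] > x_lo & fs[, 1] < x_hi &
    fs[, 2] > yr[1] & fs[, 2] < yr[2] &
    fs[, 3] > zr[1] & fs[, 3] < zr[2]
  if (any(inside)) "partially_wet" else "dry"
}
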