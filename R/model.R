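# Atom-table container and the crystal_model / expanded_lattice classes.
#
# Atoms are kept in a plain data.frame with one row per atom:
#   serial, name, elem, resname, resno, chain, x, y, z, occ, altloc,
#   het (non-ATOM record), peptide (part of a polypeptide chain), radius.
# A crystal_model bundles the atoms with the unit cell (a, b, c in angstrom,
# alpha, beta, gamma in degrees), the Hermann-Mauguin space-group symbol and
# the list of symmetry operators (rotation matrix + translation, fractional).

# Van der Waals radii (angstrom) following the CCP4 AREAIMOL defaults
# (Chothia-type united-atom values); absolute buried areas depend on this
# table, so it is fixed and exported through `vdw_radius()`.
.vdw_table <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                H = 1.00, D = 1.00, SE = 1.90, F = 1.47, CL = 1.75,
                BR = 1.85, I = 1.98)
.vdw_default <- 1.80

#' Van der Waals radius used by the package
#'
#' Returns the radius assigned to an element symbol. Unknown elements fall
#' back to 1.8 angstrom with a warning at load time.
#'
#' @param elem character vector of element symbols.
#' @return numeric vector of radii in angstrom.
#' @export
vdw_radius <- function(elem) {
  r <- .vdw_table[toupper(elem)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

# Element inference from a PDB atom name when the element column is absent.
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  e <- ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "NA", "MN"),
              two, substr(nm, 1, 1))
  e
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa1 <- stats::setNames(names(.aa3), .aa3)

aa_three <- function(one) {
  out <- .aa3[toupper(one)]
  if (anyNA(out)) stop("non-canonical residue in sequence: ",
                       paste(one[is.na(out)], collapse = ", "))
  unname(out)
}

aa_one <- function(three) {
  out <- .aa1[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), elem = character(),
             resname = character(), resno = integer(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), altloc = character(), het = logical(),
             peptide = logical(), radius = numeric(),
             stringsAsFactors = FALSE)
}

new_atoms <- function(name, elem, resname, resno, chain, xyz,
                      occ = 1, altloc = "", het = FALSE) {
  n <- length(name)
  data.frame(serial = seq_len(n), name = name, elem = elem,
             resname = resname, resno = as.integer(resno),
             chain = as.character(chain),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occ = rep_len(occ, n), altloc = rep_len(altloc, n),
             het = rep_len(het, n),
             peptide = resname %in% .aa3,
             radius = vdw_radius(elem),
             stringsAsFactors = FALSE)
}

identity_symop <- function() list(list(R = diag(3), t = c(0, 0, 0)))

#' Construct a crystal model
#'
#' @param atoms atom data.frame (see package internals).
#' @param cell numeric length-6: a, b, c (angstrom), alpha, beta, gamma (deg).
#' @param spacegroup Hermann-Mauguin symbol, e.g. "P 1" or "P 21 21 21".
#' @param symops list of symmetry operators, each `list(R = <3x3>, t = <3>)`
#'   acting on fractional coordinates. Defaults to the identity.
#' @return an object of class `crystal_model`.
#' @export
crystal_model <- function(atoms, cell, spacegroup = "P 1",
                          symops = identity_symop()) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0), length(symops) >= 1)
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, cell = as.numeric(cell),
                 spacegroup = spacegroup, symops = symops),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  pep <- x$atoms[x$atoms$peptide, ]
  cat("crystal_model:", nrow(x$atoms), "atoms,",
      length(unique(pep$chain)), "peptide chain(s)\n")
  cat(sprintf("  cell %.2f %.2f %.2f / %.1f %.1f %.1f  %s (%d symop%s)\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
              x$spacegroup, length(x$symops),
              if (length(x$symops) > 1) "s" else ""))
  invisible(x)
}

# Split a model's peptide atoms by chain, preserving atom order.
chain_atoms <- function(model, chain) {
  a <- model$atoms
  a[a$chain == chain & a$peptide, , drop = FALSE]
}

peptide_chains <- function(model) {
  unique(model$atoms$chain[model$atoms$peptide])
}

# Ordered residue sequence (one-letter) of one chain's atom table.
chain_sequence <- function(atoms) {
  res <- atoms[!duplicated(atoms$resno), c("resno", "resname")]
  res <- res[order(res$resno), ]
  paste(aa_one(res$resname), collapse = "")
}
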