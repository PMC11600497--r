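# Reading coordinate files, normalizing atoms and expanding crystal symmetry.
#
# Atom records come in through bio3d (read.pdb / read.cif); the crystal
# records that bio3d discards (CRYST1, REMARK 290 symmetry operators, the
# mmCIF _cell/_symmetry/_space_group_symop items) are parsed here. All
# downstream geometry is in orthonormal angstrom coordinates; fractional
# coordinates appear only inside the symmetry expansion.

# Parse one "x,y,z"-style symmetry operator string (e.g. "-X,Y+1/2,-Z")
# into a fractional rotation matrix and translation vector.
parse_symop_xyz <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    p <- parts[i]
    for (ax in 1:3) {
      v <- c("x", "y", "z")[ax]
      if (grepl(paste0("-", v), p, fixed = TRUE)) R[i, ax] <- -1
      else if (grepl(v, p, fixed = TRUE)) R[i, ax] <- 1
      p <- gsub(paste0("[+-]?", v), "", p)
    }
    if (nzchar(p)) {
      if (grepl("/", p)) {
        nd <- as.numeric(strsplit(sub("^\\+", "", p), "/")[[1]])
        t[i] <- nd[1] / nd[2]
      } else t[i] <- as.numeric(p)
    }
  }
  list(R = R, t = t)
}

# Minimal built-in operator sets for common oligopeptide space groups, used
# when the file carries no explicit operator records.
.sg_table <- list(
  "P 1" = c("x,y,z"),
  "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                   "-x+1/2,-y,z+1/2"),
  "C 1 2 1" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 1 2 1" = c("x,y,z", "-x,y,-z"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z")
)

spacegroup_ops <- function(symbol) {
  key <- toupper(trimws(symbol))
  key <- sub("^P21$", "P 1 21 1", key)
  key <- sub("^P 21$", "P 1 21 1", key)
  ops <- .sg_table[[key]]
  if (is.null(ops)) return(NULL)
  lapply(ops, parse_symop_xyz)
}

bio3d_to_atoms <- function(at) {
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- guess_element(at$elety[miss])
  known <- elem %in% names(.vdw_table) |
    at$resid %in% .aa3 | at$resid %in% c("HOH", "WAT", "DOD")
  if (any(!known))
    warning("unknown residue/element for ", sum(!known),
            " atom(s); fallback van der Waals radius 1.8 angstrom used")
  a <- new_atoms(name = trimws(at$elety), elem = elem,
                 resname = trimws(at$resid), resno = at$resno,
                 chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                 xyz = cbind(at$x, at$y, at$z),
                 occ = ifelse(is.na(at$o), 1, at$o),
                 altloc = ifelse(is.na(at$alt), "", at$alt),
                 het = at$type != "ATOM")
  a
}

#' Load a crystal structure
#'
#' Reads a PDB or mmCIF file into a [crystal_model()], including the unit
#' cell and the space-group symmetry operators. Operators are taken from the
#' file itself (REMARK 290 SMTRY records or the _space_group_symop loop)
#' when present, otherwise from a small built-in table of common space
#' groups.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by file extension).
#' @return a `crystal_model`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") load_pdb(path) else load_mmcif(path)
}

load_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("missing unit cell (no CRYST1 record) in ", path)
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  if (anyNA(cell) || any(cell[1:3] <= 0))
    stop("missing unit cell (unreadable CRYST1 record) in ", path)
  sg <- trimws(substr(cr[1], 56, 66))
  if (!nzchar(sg)) stop("missing space group symbol on CRYST1 record in ", path)
  smtry <- grep("^REMARK 290 +SMTRY", lines, value = TRUE)
  if (length(smtry)) {
    # SMTRY records express the operators in orthogonal angstrom
    # coordinates; convert to fractional for the expansion machinery
    tok <- strsplit(trimws(substr(smtry, 12, 80)), "[[:space:]]+")
    rowno <- as.integer(sub("SMTRY", "", vapply(tok, `[`, character(1), 1)))
    opno <- vapply(tok, function(x) as.numeric(x[2]), numeric(1))
    M <- cell_orth_matrix(cell); Minv <- solve(M)
    ops <- lapply(unique(opno), function(k) {
      rows <- tok[opno == k][order(rowno[opno == k])]
      Rc <- do.call(rbind, lapply(rows, function(x) as.numeric(x[3:5])))
      tc <- vapply(rows, function(x) as.numeric(x[6]), numeric(1))
      list(R = round(Minv %*% Rc %*% M, 10), t = round(Minv %*% tc, 10)[, 1])
    })
  } else {
    ops <- spacegroup_ops(sg)
    if (is.null(ops)) {
      warning("no symmetry operators for space group '", sg,
              "'; using identity only")
      ops <- identity_symop()
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  crystal_model(bio3d_to_atoms(pdb$atom), cell, sg, ops)
}

cif_item <- function(lines, name) {
  hit <- grep(paste0("^", name, "[[:space:]]"), lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  val <- trimws(sub(paste0("^", name), "", hit[1]))
  gsub("^['\"]|['\"]$", "", val)
}

load_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- as.numeric(c(cif_item(lines, "_cell.length_a"),
                       cif_item(lines, "_cell.length_b"),
                       cif_item(lines, "_cell.length_c"),
                       cif_item(lines, "_cell.angle_alpha"),
                       cif_item(lines, "_cell.angle_beta"),
                       cif_item(lines, "_cell.angle_gamma")))
  if (anyNA(cell)) stop("missing unit cell (_cell items) in ", path)
  sg <- cif_item(lines, "_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- cif_item(lines, "_space_group.name_H-M_alt")
  if (is.na(sg)) stop("missing space group in ", path)
  # operator loop, if present
  opi <- grep("_space_group_symop.operation_xyz|_symmetry_equiv.pos_as_xyz",
              lines)
  ops <- NULL
  if (length(opi)) {
    j <- opi[1] + 1
    vals <- character(0)
    while (j <= length(lines) && !grepl("^(_|loop_|#)", lines[j]) &&
           nzchar(trimws(lines[j]))) {
      tok <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]]
      vals <- c(vals, gsub("'", "", tok[grepl(",", tok)][1]))
      j <- j + 1
    }
    vals <- vals[!is.na(vals)]
    if (length(vals)) ops <- lapply(vals, parse_symop_xyz)
  }
  if (is.null(ops)) {
    ops <- spacegroup_ops(sg)
    if (is.null(ops)) {
      warning("no symmetry operators for space group '", sg,
              "'; using identity only")
      ops <- identity_symop()
    }
  }
  # read.cif is marked beta upstream and warns on minimal files; the
  # warnings carry no actionable information here
  cif <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  crystal_model(bio3d_to_atoms(cif$atom), cell, sg, ops)
}

#' Normalize a crystal model for interface analysis
#'
#' Removes hydrogen/deuterium atoms; of each alternative-conformation group
#' keeps only the highest-occupancy conformer (ties broken by the
#' alphabetically first altloc id) and clears its altloc flag. Solvent and
#' other non-peptide molecules are retained, tagged non-peptide. Idempotent.
#'
#' @param model a `crystal_model`.
#' @return the sanitized `crystal_model`.
#' @export
sanitize <- function(model) {
  a <- model$atoms
  a <- a[!(a$elem %in% c("H", "D")), , drop = FALSE]
  if (any(nzchar(a$altloc))) {
    key <- paste(a$chain, a$resno, a$resname, a$name, sep = "|")
    keep <- rep(TRUE, nrow(a))
    for (k in unique(key[nzchar(a$altloc)])) {
      i <- which(key == k)
      if (length(i) > 1 || nzchar(a$altloc[i[1]])) {
        best <- i[order(-a$occ[i], a$altloc[i])][1]
        keep[setdiff(i, best)] <- FALSE
      }
    }
    a <- a[keep, , drop = FALSE]
    a$altloc <- ""
  }
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  model$atoms <- a
  model
}

#' Expand crystal symmetry around the asymmetric unit
#'
#' Generates every symmetry/lattice copy of each chain that has any atom
#' within `radius` of any asymmetric-unit atom. Lattice translations are
#' searched over -2..+2 cells in each direction; coordinates are returned in
#' the orthonormal frame of the asymmetric unit.
#'
#' @param model a sanitized `crystal_model`.
#' @param radius contact search radius in angstrom (> 0).
#' @param max_copies hard cap on the number of generated copies.
#' @return an `expanded_lattice`: atoms of all retained copies (column
#'   `copy` identifies the chain copy) plus a provenance table `copies`.
#' @export
expand_symmetry <- function(model, radius = 8, max_copies = 2000) {
  stopifnot(radius > 0)
  M <- cell_orth_matrix(model$cell)
  Minv <- solve(M)
  au <- model$atoms
  au_xyz <- coords_of(au)
  au_ctr <- colMeans(au_xyz)
  au_rad <- sqrt(max(rowSums(sweep(au_xyz, 2, au_ctr)^2)))

  chains <- unique(au$chain)
  out_atoms <- list(); prov <- list(); cid <- 0L
  seen <- character(0)
  tr <- as.matrix(expand.grid(u = -2:2, v = -2:2, w = -2:2))
  for (ch in chains) {
    ca <- au[au$chain == ch, , drop = FALSE]
    fx <- coords_of(ca) %*% t(Minv)
    ch_rad_f <- NULL
    for (k in seq_along(model$symops)) {
      op <- model$symops[[k]]
      fr <- fx %*% t(op$R)
      fr <- sweep(fr, 2, -op$t)
      for (j in seq_len(nrow(tr))) {
        frt <- sweep(fr, 2, -as.numeric(tr[j, ]))
        cart <- frt %*% t(M)
        ctr <- colMeans(cart)
        ch_rad <- sqrt(max(rowSums(sweep(cart, 2, ctr)^2)))
        if (vnorm(ctr - au_ctr) > radius + au_rad + ch_rad) next
        if (cpp_min_dist(cart, au_xyz, 0) > radius) next
        sig <- paste(ch, paste(round(c(ctr, cart[1, ]), 3), collapse = ","))
        if (sig %in% seen) next
        seen <- c(seen, sig)
        cid <- cid + 1L
        if (cid > max_copies) stop("symmetry expansion exceeds max_copies (",
                                   max_copies, "); reduce radius")
        cc <- ca
        cc <- set_coords(cc, cart)
        cc$copy <- cid
        out_atoms[[cid]] <- cc
        prov[[cid]] <- data.frame(copy = cid, chain = ch, op = k,
                                  t1 = tr[j, 1], t2 = tr[j, 2], t3 = tr[j, 3],
                                  identity = (k == 1 && all(tr[j, ] == 0)))
      }
    }
  }
  atoms <- do.call(rbind, out_atoms)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, copies = do.call(rbind, prov),
                 cell = model$cell, spacegroup = model$spacegroup,
                 model = model),
            class = "expanded_lattice")
}

#' @export
print.expanded_lattice <- function(x, ...) {
  cat("expanded_lattice:", nrow(x$copies), "chain copies,",
      nrow(x$atoms), "atoms (", sum(x$copies$identity),
      "asymmetric-unit chains )\n")
  invisible(x)
}

# Treat a plain model (e.g. a finite fixture sheet) as a trivial lattice:
# every chain is its own identity copy.
as_lattice <- function(x) {
  if (inherits(x, "expanded_lattice")) return(x)
  stopifnot(inherits(x, "crystal_model"))
  a <- x$atoms
  chains <- unique(a$chain)
  a$copy <- match(a$chain, chains)
  structure(list(atoms = a,
                 copies = data.frame(copy = seq_along(chains), chain = chains,
                                     op = 1L, t1 = 0L, t2 = 0L, t3 = 0L,
                                     identity = TRUE),
                 cell = x$cell, spacegroup = x$spacegroup, model = x),
            class = "expanded_lattice")
}

#' Write a model or expanded lattice to a PDB file
#'
#' Standard CRYST1 + ATOM/HETATM records; chain identifiers of lattice
#' copies are remapped to single characters with the provenance recorded in
#' REMARK 300 lines.
#'
#' @param x `crystal_model` or `expanded_lattice`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "expanded_lattice")) {
    a <- x$atoms
    ids <- c(LETTERS, letters, 0:9)
    a$chain <- ids[((a$copy - 1) %% length(ids)) + 1]
    cell <- x$cell; sg <- x$spacegroup
    prov <- sprintf("REMARK 300 COPY %d CHAIN %s OP %d T %d %d %d",
                    x$copies$copy, x$copies$chain, x$copies$op,
                    x$copies$t1, x$copies$t2, x$copies$t3)
  } else {
    a <- x$atoms; cell <- x$cell; sg <- x$spacegroup; prov <- character(0)
  }
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
            cell[1], cell[2], cell[3], cell[4], cell[5], cell[6], sg, 1),
    prov,
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"),
            (seq_len(nrow(a)) - 1) %% 99999 + 1,
            ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
            a$altloc, a$resname, substr(a$chain, 1, 1), a$resno,
            a$x, a$y, a$z, a$occ, 0, a$elem),
    "END")
  writeLines(lines, path)
  invisible(path)
}
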