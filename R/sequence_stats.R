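# Primary/secondary-structure analytics: backbone dihedrals and Ramachandran
# assignment, residue composition, GRAVY and difference-GRAVY.

# Kyte-Doolittle hydropathy values.
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# The beta region of the Ramachandran surface, as an explicit set of
# (phi, psi) rectangles (wrap-aware in psi). "allowed" approximates the
# broad beta-sheet region; "favored" the core of it.
.beta_regions <- list(
  allowed = list(c(-180, -45, 45, 180), c(-180, -45, -180, -150)),
  favored = list(c(-170, -60, 90, 180), c(-170, -60, -180, -170))
)

wrap_interval_dist <- function(x, lo, hi) {
  # distance (degrees, wrap-aware on the 360 circle) from x to [lo, hi]
  d <- ifelse(x >= lo & x <= hi, 0, pmin(
    pmin(abs(x - lo), 360 - abs(x - lo)),
    pmin(abs(x - hi), 360 - abs(x - hi))))
  d
}

#' Distance to the beta region of the Ramachandran surface
#'
#' Wrap-aware Euclidean distance in (phi, psi) angle space from each point
#' to the configured beta region; 0 for points inside.
#'
#' @param phi,psi numeric vectors, degrees.
#' @param region "allowed" or "favored".
#' @return numeric vector of distances in degrees.
#' @export
beta_region_distance <- function(phi, psi, region = "allowed") {
  rects <- .beta_regions[[match.arg(region, names(.beta_regions))]]
  d <- rep(Inf, length(phi))
  for (r in rects) {
    dp <- wrap_interval_dist(phi, r[1], r[2])
    ds <- wrap_interval_dist(psi, r[3], r[4])
    d <- pmin(d, sqrt(dp^2 + ds^2))
  }
  d
}

#' Backbone dihedral angles of one chain
#'
#' Standard phi/psi from consecutive backbone atoms, with Ramachandran
#' region assignment ("beta" inside the allowed beta region, terminal
#' residues unassigned). Residues with missing backbone atoms are skipped
#' with a warning.
#'
#' @param atoms atom table of one chain (>= 3 residues).
#' @return data.frame: chain, resno, resname, phi, psi, region, beta_favored.
#' @export
backbone_dihedrals <- function(atoms) {
  res <- sort(unique(atoms$resno))
  if (length(res) < 3) stop("chain too short for dihedral analysis (< 3 residues)")
  g <- function(r, nm) {
    i <- which(atoms$resno == r & atoms$name == nm)[1]
    if (is.na(i)) return(NULL)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  out <- list()
  for (k in seq_along(res)) {
    r <- res[k]
    N <- g(r, "N"); CA <- g(r, "CA"); C <- g(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      warning("residue ", r, " skipped: missing backbone atom")
      next
    }
    phi <- psi <- NA_real_
    if (k > 1 && res[k - 1] == r - 1) {
      Cp <- g(r - 1, "C")
      if (!is.null(Cp)) phi <- dihedral_angle(Cp, N, CA, C)
    }
    if (k < length(res) && res[k + 1] == r + 1) {
      Nn <- g(r + 1, "N")
      if (!is.null(Nn)) psi <- dihedral_angle(N, CA, C, Nn)
    }
    region <- if (is.na(phi) || is.na(psi)) "unassigned-terminal"
    else if (beta_region_distance(phi, psi) == 0) "beta" else "other"
    out[[length(out) + 1]] <- data.frame(
      chain = atoms$chain[atoms$resno == r][1], resno = r,
      resname = atoms$resname[atoms$resno == r][1],
      phi = phi, psi = psi, region = region,
      beta_favored = !is.na(phi) && !is.na(psi) &&
        beta_region_distance(phi, psi, "favored") == 0)
  }
  do.call(rbind, out)
}

#' GRAVY index of a sequence
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values.
#'
#' @param sequence one-letter amino-acid string.
#' @return mean hydropathy.
#' @export
gravy <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  if (!length(s)) stop("empty sequence")
  v <- .kd[toupper(s)]
  if (anyNA(v)) stop("unknown residue in sequence: ",
                     paste(s[is.na(v)], collapse = ""))
  mean(v)
}

#' Difference-GRAVY of a hexapeptide
#'
#' Absolute difference between the GRAVY of residues 1,3,5 and residues
#' 2,4,6 — the two faces of an in-register hexapeptide beta-strand.
#'
#' @param sequence one-letter string of length exactly 6.
#' @return non-negative difference of face hydropathies.
#' @export
difference_gravy <- function(sequence) {
  if (nchar(sequence) != 6) stop("difference-GRAVY is defined for hexapeptides")
  s <- strsplit(sequence, "")[[1]]
  abs(gravy(paste(s[c(1, 3, 5)], collapse = "")) -
        gravy(paste(s[c(2, 4, 6)], collapse = "")))
}

#' Residue composition and propensities of a structure set
#'
#' Keeps one representative per identical sequence, then tabulates residue
#' counts and relative frequencies, overall and per subset, with the
#' propensity ratio subset-frequency / overall-frequency.
#'
#' @param sequences character vector of one-letter sequences.
#' @param subset optional factor/character of the same length (e.g.
#'   "parallel"/"antiparallel").
#' @return a `composition_table`: data.frame with residue, counts and
#'   frequencies (overall and per subset) and propensity ratios.
#' @export
composition_report <- function(sequences, subset = NULL) {
  if (!length(sequences)) stop("empty structure set")
  keep <- !duplicated(sequences)
  sequences <- sequences[keep]
  if (!is.null(subset)) subset <- subset[keep]
  split_res <- function(seqs) factor(unlist(strsplit(toupper(seqs), "")),
                                     levels = names(.kd))
  all_tab <- table(split_res(sequences))
  out <- data.frame(residue = names(all_tab),
                    count = as.integer(all_tab),
                    frequency = as.numeric(all_tab / sum(all_tab)))
  if (!is.null(subset)) {
    for (lv in unique(subset)) {
      tab <- table(split_res(sequences[subset == lv]))
      fr <- as.numeric(tab / max(1, sum(tab)))
      out[[paste0("count_", lv)]] <- as.integer(tab)
      out[[paste0("frequency_", lv)]] <- fr
      out[[paste0("propensity_", lv)]] <-
        ifelse(out$frequency > 0, fr / out$frequency, NA_real_)
    }
  }
  class(out) <- c("composition_table", "data.frame")
  out
}

# 4x4-degree binned Ramachandran histogram (export helper).
ramachandran_bins <- function(dihedrals, bin = 4) {
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  br <- seq(-180, 180, by = bin)
  tab <- table(cut(dihedrals$phi[ok], br), cut(dihedrals$psi[ok], br))
  tab
}
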