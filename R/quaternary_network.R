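# Crystal-wide network of zipper interfaces: 1D (isolated sandwiches),
# 2D (catemer layers) or 3D (brick-like), with a packing-pattern tag.
#
# Dimensionality follows the per-sheet interface count in the lattice:
# a sheet whose single face forms one zipper belongs to an isolated
# sandwich (1D); a sheet zippered on both faces extends a catemer layer
# (2D); a sheet forming more than two interfaces (staggered, brick-like
# packing) knits a 3D network. Degrees are evaluated on sheet instances of
# the expanded lattice whose contact neighbourhood is complete (those
# containing asymmetric-unit chains).

#' Build the interface graph of a crystal
#'
#' Nodes are the beta-sheet instances of the expanded lattice; edges are
#' admitted zipper interface observations between them, annotated with the
#' contact direction, the lateral shift along the strand direction and the
#' contacted face of each sheet. Symmetry-unique sheets share a `label`.
#'
#' @param lattice the `expanded_lattice`.
#' @param sheets list of `beta_sheet`s of the lattice.
#' @param interfaces list of admitted `zipper_interface` observations
#'   (before deduplication).
#' @param pairs list of index pairs into `sheets`, parallel to `interfaces`.
#' @return an `interface_graph`.
#' @export
build_interface_graph <- function(lattice, sheets, interfaces, pairs) {
  stopifnot(length(interfaces) == length(pairs))
  lattice <- as_lattice(lattice)
  prov <- lattice$copies
  a <- lattice$atoms[lattice$atoms$peptide, , drop = FALSE]
  label <- vapply(sheets, function(s)
    paste(sort(unique(prov$chain[match(s$copies, prov$copy)])), collapse = "+"),
    character(1))
  has_identity <- vapply(sheets, function(s)
    any(prov$identity[match(s$copies, prov$copy)]), logical(1))
  edges <- list()
  for (i in seq_along(interfaces)) {
    intf <- interfaces[[i]]
    ia <- pairs[[i]][1]; ib <- pairs[[i]][2]
    sa <- sheets[[ia]]; sb <- sheets[[ib]]
    ctr_a <- colMeans(coords_of(a[a$copy %in% sa$copies, ]))
    ctr_b <- colMeans(coords_of(a[a$copy %in% sb$copies, ]))
    dirv <- ctr_b - ctr_a
    edges[[i]] <- data.frame(
      from = ia, to = ib, interface = i,
      dx = dirv[1], dy = dirv[2], dz = dirv[3],
      shift = abs(sum(dirv * sa$strand_dir)),
      side_from = sign(sum(sa$axis_x * dirv)),
      side_to = sign(-sum(sb$axis_x * dirv)),
      class_id = intf$topology$class_id,
      key = intf$residues_key,
      stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer())
  g <- igraph::graph_from_data_frame(
    ed[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_along(sheets)))
  structure(list(graph = g, edges = ed, label = label,
                 has_identity = has_identity, n_sheets = length(sheets)),
            class = "interface_graph")
}

#' @export
print.interface_graph <- function(x, ...) {
  cat("interface_graph:", x$n_sheets, "sheet instances,",
      nrow(x$edges), "interface observation(s)\n")
  invisible(x)
}

#' Classify the quaternary interface network
#'
#' @param graph an `interface_graph`.
#' @param chain_length residues per peptide chain (for shift thresholds).
#' @param larks any LARKS chains present (tags the pattern basket-weave).
#' @param straight_frac,brick_frac lateral-shift fractions of the chain
#'   length bounding the straight and brick patterns.
#' @return list(dimensionality, pattern, degrees) — degrees over the
#'   complete-neighbourhood sheet instances.
#' @export
classify_network <- function(graph, chain_length = 6, larks = FALSE,
                             straight_frac = 0.15, brick_frac = 0.35) {
  ed <- graph$edges
  core <- which(graph$has_identity)
  if (!nrow(ed) || !length(core)) {
    return(list(dimensionality = "0D", pattern = "none",
                degrees = stats::setNames(numeric(0), character(0))))
  }
  deg <- stats::setNames(numeric(length(core)), core)
  two_sided <- stats::setNames(logical(length(core)), core)
  for (k in seq_along(core)) {
    n <- core[k]
    inc <- ed[ed$from == n | ed$to == n, , drop = FALSE]
    if (!nrow(inc)) next
    partner <- ifelse(inc$from == n, inc$to, inc$from)
    sides <- ifelse(inc$from == n, inc$side_from, inc$side_to)
    deg[k] <- length(unique(partner))
    two_sided[k] <- length(unique(sides[sides != 0])) == 2
  }
  dmax <- max(deg)
  dim <- if (dmax <= 1) "1D"
  else if (dmax == 2 && any(two_sided)) "2D"
  else if (dmax == 2) "2D"
  else "3D"

  rise <- 3.35
  frac <- if (chain_length > 0) ed$shift / (chain_length * rise) else 0
  pattern <- if (larks) "basket-weave"
  else if (dim == "3D") "brick"
  else if (all(frac < straight_frac)) "straight"
  else if (any(frac > brick_frac)) "brick"
  else "tilted"
  list(dimensionality = dim, pattern = pattern, degrees = deg)
}
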