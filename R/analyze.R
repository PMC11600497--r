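# Top-level analysis driver: one call runs the full pipeline on a crystal
# (file or model) and returns a structured report; a set of reports can be
# summarized into database-level tables.

#' Analyze one amyloid oligopeptide crystal
#'
#' Runs the full pipeline: sanitize, expand crystal symmetry, detect
#' backbone H-bonds, assemble beta-sheets, enumerate and admit zipper
#' interfaces, compute the Sc / Ab / SDi descriptors, deduplicate
#' symmetry-equivalent interfaces, tag wetness, and classify the quaternary
#' interface network.
#'
#' @param x file path, `crystal_model` or `expanded_lattice`.
#' @param expansion_radius symmetry-expansion contact radius, angstrom.
#' @param probe_radius solvent probe radius, angstrom.
#' @param hbond_dmax,hbond_angle_min H-bond criteria.
#' @param descriptors compute Sc/Ab/SDi per interface (switch off for a
#'   topology-only run).
#' @param network classify the interface network.
#' @param id structure identifier for the report.
#' @param ... further admission thresholds passed to [admit_interface()].
#' @return a `zipper_report`.
#' @export
analyze_crystal <- function(x, expansion_radius = 8, probe_radius = 1.4,
                            hbond_dmax = 3.5, hbond_angle_min = 120,
                            descriptors = TRUE, network = TRUE,
                            id = NULL, ...) {
  if (is.character(x)) {
    if (is.null(id)) id <- sub("\\.(pdb|cif|ent)$", "", basename(x),
                               ignore.case = TRUE)
    x <- load_structure(x)
  }
  if (is.null(id)) id <- "structure"
  if (inherits(x, "crystal_model")) {
    model <- sanitize(x)
    lattice <- expand_symmetry(model, radius = expansion_radius)
  } else {
    lattice <- as_lattice(x)
  }
  hbonds <- detect_backbone_hbonds(lattice, d_max = hbond_dmax,
                                   angle_min = hbond_angle_min)
  sheets <- assemble_sheets(lattice, hbonds)
  pairs <- find_contacting_pairs(sheets, lattice, probe_radius)
  admitted <- list(); admitted_pairs <- list(); rejected <- list()
  for (p in pairs) {
    r <- admit_interface(sheets[[p[1]]], sheets[[p[2]]], lattice, hbonds,
                         probe_radius = probe_radius,
                         descriptors = descriptors, ...)
    if (isTRUE(r$admitted)) {
      r$wet <- classify_wetness(r, lattice)
      admitted[[length(admitted) + 1]] <- r
      admitted_pairs[[length(admitted_pairs) + 1]] <- p
    } else {
      rejected[[length(rejected) + 1]] <-
        data.frame(i = p[1], j = p[2],
                   criterion = if (is.null(r$criterion)) NA_integer_ else r$criterion,
                   reason = r$reason)
    }
  }
  unique_ifaces <- deduplicate(admitted)

  # per-chain sequence / conformation statistics on the asymmetric unit
  au <- lattice$atoms[lattice$atoms$peptide &
                        lattice$atoms$copy %in%
                        lattice$copies$copy[lattice$copies$identity], ,
                      drop = FALSE]
  seqs <- vapply(split(au, au$copy), chain_sequence, character(1))
  dihedrals <- do.call(rbind, lapply(split(au, au$copy), function(ch) {
    if (length(unique(ch$resno)) >= 3) backbone_dihedrals(ch) else NULL
  }))
  larks_any <- any(vapply(split(au, au$copy), function(ch) {
    if (length(unique(ch$resno)) >= 4) detect_larks(ch) else FALSE
  }, logical(1)))

  net <- NULL
  if (network && length(admitted)) {
    gr <- build_interface_graph(lattice, sheets, admitted, admitted_pairs)
    net <- classify_network(gr, chain_length = max(nchar(seqs)),
                            larks = larks_any)
    net$graph <- gr
  }

  iface_tab <- if (length(unique_ifaces)) do.call(rbind, lapply(
    unique_ifaces, function(u) {
      data.frame(id = id,
                 residues = u$residues_label,
                 class = u$topology$class_id,
                 arrangement = u$topology$arrangement,
                 pseudo = u$topology$pseudo,
                 oor = u$topology$oor,
                 larks = u$topology$larks,
                 Sc = if (is.null(u$descriptors)) NA_real_ else round(u$descriptors$Sc, 2),
                 Ab = if (is.null(u$descriptors)) NA_real_ else round(u$descriptors$Ab, 1),
                 SDi = if (is.null(u$descriptors)) NA_real_ else round(u$descriptors$SDi, 2),
                 wet = u$wet,
                 multiplicity = u$multiplicity,
                 stringsAsFactors = FALSE)
    })) else NULL

  structure(list(
    id = id, lattice = lattice, hbonds = hbonds, sheets = sheets,
    interfaces = unique_ifaces, observations = admitted,
    rejections = if (length(rejected)) do.call(rbind, rejected) else NULL,
    interface_table = iface_tab,
    sequences = seqs, dihedrals = dihedrals, larks = larks_any,
    network = net),
    class = "zipper_report")
}

#' @export
print.zipper_report <- function(x, ...) {
  cat("zipper_report:", x$id, "\n")
  cat("  ", length(x$sheets), "beta-sheet(s),",
      nrow(x$hbonds), "backbone H-bonds,",
      length(x$interfaces), "unique zipper interface(s)\n")
  if (!is.null(x$interface_table)) {
    print(x$interface_table[, c("residues", "class", "Sc", "Ab", "SDi",
                                "wet", "multiplicity")], row.names = FALSE)
  }
  if (!is.null(x$network)) {
    cat("  network:", x$network$dimensionality, "/", x$network$pattern, "\n")
  }
  invisible(x)
}

#' @export
summary.zipper_report <- function(object, ...) {
  br <- if (!is.null(object$dihedrals)) {
    d <- object$dihedrals[!is.na(object$dihedrals$phi) &
                            !is.na(object$dihedrals$psi), ]
    mean(d$region == "beta")
  } else NA_real_
  out <- list(id = object$id,
              n_sheets = length(object$sheets),
              n_interfaces = length(object$interfaces),
              beta_fraction = br,
              network = if (is.null(object$network)) NA_character_
              else object$network$dimensionality,
              sequences = unique(object$sequences))
  class(out) <- "summary.zipper_report"
  out
}

#' @export
print.summary.zipper_report <- function(x, ...) {
  cat(x$id, ":", x$n_interfaces, "interface(s),",
      x$n_sheets, "sheet(s), beta fraction",
      sprintf("%.2f", x$beta_fraction), ", network", x$network, "\n")
  invisible(x)
}

#' Database-level summary over several reports
#'
#' Class populations, composition/propensity tables (unique sequences
#' only), descriptor distributions and parallel-vs-antiparallel means.
#'
#' @param reports list of `zipper_report`s.
#' @return a `zipper_summary` list of tables.
#' @export
summarize_reports <- function(reports) {
  if (!length(reports)) stop("empty run: no reports to summarize")
  tabs <- do.call(rbind, lapply(reports, `[[`, "interface_table"))
  seq_arr <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$interface_table)) return(NULL)
    data.frame(sequence = r$sequences[1],
               arrangement = r$interface_table$arrangement[1])
  }))
  comp <- if (!is.null(seq_arr))
    composition_report(seq_arr$sequence, seq_arr$arrangement) else NULL
  by_arr <- NULL
  if (!is.null(tabs)) {
    by_arr <- do.call(rbind, lapply(split(tabs, tabs$arrangement), function(d)
      data.frame(arrangement = d$arrangement[1], n = nrow(d),
                 mean_Sc = mean(d$Sc, na.rm = TRUE),
                 mean_Ab = mean(d$Ab, na.rm = TRUE),
                 mean_SDi = mean(d$SDi, na.rm = TRUE))))
  }
  structure(list(
    interfaces = tabs,
    n_structures = length(reports),
    n_interfaces = if (is.null(tabs)) 0L else nrow(tabs),
    class_population = if (is.null(tabs)) NULL else table(tabs$class),
    composition = comp,
    by_arrangement = by_arr,
    mean_SDi = if (is.null(tabs)) NA_real_ else mean(tabs$SDi, na.rm = TRUE)),
    class = "zipper_summary")
}

#' @export
print.zipper_summary <- function(x, ...) {
  cat("zipper_summary:", x$n_structures, "structures,",
      x$n_interfaces, "unique interfaces\n")
  if (!is.null(x$by_arrangement)) print(x$by_arrangement, row.names = FALSE)
  invisible(x)
}

#' Write report tables to CSV/JSON
#'
#' @param report a `zipper_report` or `zipper_summary`.
#' @param dir output directory (created if needed).
#' @param formats subset of c("csv", "json").
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tab <- if (inherits(report, "zipper_report")) report$interface_table
  else report$interfaces
  base <- if (inherits(report, "zipper_report")) report$id else "summary"
  if ("csv" %in% formats && !is.null(tab)) {
    p <- file.path(dir, paste0(base, "_interfaces.csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, paste0(base, ".json"))
    obj <- if (inherits(report, "zipper_report")) {
      list(id = report$id,
           interfaces = tab,
           network = if (is.null(report$network)) NULL else
             report$network[c("dimensionality", "pattern")],
           sequences = report$sequences)
    } else {
      list(n_structures = report$n_structures,
           n_interfaces = report$n_interfaces,
           mean_SDi = report$mean_SDi,
           by_arrangement = report$by_arrangement,
           interfaces = tab)
    }
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a fixture crystal to a PDB file
#'
#' Deterministic: identical arguments give byte-identical files.
#'
#' @param class_id topology class 1-8 (classes 9/10 have no published
#'   construction and are refused).
#' @param sequence one-letter sequence.
#' @param path output PDB path.
#' @param ... further arguments to [sheet_spec()] / [zipper_spec()].
#' @return invisibly, the path.
#' @export
generate_fixture <- function(class_id, sequence, path, ...) {
  if (class_id %in% c(9, 10))
    stop("classes 9/10 construction unsupported (no such structure has been observed)")
  arr <- if (class_id <= 4) "parallel" else "antiparallel"
  dots <- list(...)
  sargs <- dots[names(dots) %in% names(formals(sheet_spec))]
  zargs <- dots[names(dots) %in% setdiff(names(formals(zipper_spec)),
                                         c("class_id", "sheet_spec"))]
  ss <- do.call(sheet_spec, c(list(sequence = sequence, arrangement = arr),
                              sargs))
  zs <- do.call(zipper_spec, c(list(class_id = class_id, sheet_spec = ss),
                               zargs))
  write_pdb(build_zipper(zs), path)
}
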