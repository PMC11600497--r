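# Shared fixtures, built once per test run and cached. Everything is
# deterministic: no seeds, no randomness.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_parallel_sheet <- function() fx("par_sheet", function()
  build_sheet(sheet_spec("AAAAAA", n_strands = 5, arrangement = "parallel")))

fx_antiparallel_sheet <- function() fx("anti_sheet", function()
  build_sheet(sheet_spec("AAAAAA", n_strands = 6,
                         arrangement = "antiparallel")))

fx_zipper <- function(class_id, sequence = "LYIQWL", ...) {
  key <- paste0("zip_", class_id, "_", sequence,
                paste(c(...), collapse = "_"))
  arr <- if (class_id <= 4) "parallel" else "antiparallel"
  fx(key, function()
    build_zipper(zipper_spec(class_id,
                             sheet_spec(sequence, arrangement = arr), ...)))
}

# expanded lattice + H-bonds + sheets for a model, cached by key
fx_pipeline <- function(key, model) {
  fx(paste0("pl_", key), function() {
    lat <- expand_symmetry(sanitize(model), radius = 8)
    hb <- detect_backbone_hbonds(lat)
    sheets <- assemble_sheets(lat, hb)
    list(lat = lat, hb = hb, sheets = sheets)
  })
}

# the two sheets holding asymmetric-unit chains (the designed zipper pair)
identity_sheet_pair <- function(pl) {
  idc <- pl$lat$copies$copy[pl$lat$copies$identity]
  si <- which(vapply(pl$sheets, function(s) any(s$copies %in% idc),
                     logical(1)))
  stopifnot(length(si) >= 2)
  si[1:2]
}

fx_slab <- function(class_id, sequence = "LYIQWL", ...) {
  key <- paste0("slab_", class_id, "_", sequence)
  fx(key, function() {
    z <- fx_zipper(class_id, sequence, ...)
    pl <- fx_pipeline(paste0(class_id, "_", sequence), z)
    si <- identity_sheet_pair(pl)
    select_slab(pl$sheets[[si[1]]], pl$sheets[[si[2]]], pl$lat)
  })
}

# H-bond count of the interior chain of a finite fixture sheet
interior_chain_hbonds <- function(sheet_model) {
  hb <- detect_backbone_hbonds(sheet_model)
  lat <- stericzipper:::as_lattice(sheet_model)
  a <- lat$atoms
  # interior = strand whose centroid is nearest the sheet centroid
  ctr <- vapply(split(a, a$copy), function(d) mean(d$y), numeric(1))
  mid <- as.integer(names(ctr)[which.min(abs(ctr - mean(range(ctr))))])
  sum(hb$don_copy == mid) + sum(hb$acc_copy == mid)
}
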