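Package: stericzipper
Title: Steric-Zipper Interface Analysis of Amyloid Oligopeptide Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects beta-sheets and steric-zipper interfaces in single-crystal
    structures of short aggregation-prone peptides, assigns amyloid topology
    classes (1-8, with out-of-register and LARKS auxiliary labels), and computes
    three interface descriptors: per-chain buried area (Ab) on a standardized
    three-repeating-unit slab, shape complementarity (Sc) of the facing
    molecular surfaces, and the Surface Detail Index (SDi), the ratio of the
    buried interface area to its flat rectangular footprint. Includes
    crystal-symmetry expansion from PDB/mmCIF records, a deterministic
    generator of ideal synthetic beta-sheet crystals with known ground-truth
    topology, sequence and backbone-conformation statistics (composition,
    GRAVY, Ramachandran assignment), and 1D/2D/3D classification of the
    crystal-wide network of zipper interfaces.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
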