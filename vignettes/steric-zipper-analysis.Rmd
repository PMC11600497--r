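---
title: "Steric-zipper interface analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric-zipper interface analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stericzipper)
```

## The problem

Short aggregation-prone peptides (3–11 residues) crystallize as stacks of
quasi-infinite β-sheets whose facing side chains interlock into dry,
tightly packed interfaces — steric zippers — the same structural motif
that forms the spine of amyloid fibrils. A single crystal contains one or
a few peptide chains in its asymmetric unit; the β-sheets, the zipper
interfaces and the crystal-wide packing emerge only after expanding the
crystallographic symmetry. This package reconstructs that hierarchy:

1. **primary** – sequence composition, hydropathy (GRAVY), difference-GRAVY
   between the two faces of a hexapeptide;
2. **secondary** – backbone (φ, ψ) conformation and the β-region fraction;
3. **tertiary** – which β-sheet pairs form admissible zipper interfaces,
   their topology class (1–8, plus out-of-register and LARKS auxiliary
   labels) and three interface descriptors: shape complementarity (Sc),
   per-chain buried area (Ab) and the Surface Detail Index (SDi);
4. **quaternary** – whether the zipper connections form a 1D, 2D or 3D
   network through the crystal.

## Coordinate conventions

All analysis happens in orthonormal ångström coordinates; fractional
coordinates are used only inside the symmetry expansion. In the idealized
construction frame, strands run along *z*, strands of one sheet stack
along *y* (the fibril axis) at ~4.8 Å, and two sheets of a zipper face
each other along *x*. Assembled sheets carry their own measured axes, so
none of the analysis relies on a structure being axis-aligned.

## Sheet assembly and topology classes

Chains are assigned to β-sheets through inter-backbone H-bonds. Because
models are analyzed without hydrogens (they are stripped together with
alternative conformations during sanitization), an H-bond is a geometric
N···O=C contact: N···O ≤ 3.5 Å and a C=O···N angle ≥ 120°, both
configurable. Strand pairs sharing at least two such bonds are sheet
neighbours; connected components are sheets. These cutoffs are standard
geometric criteria; on ideal in-register sheets any reasonable choice
finds the same canonical counts — 10 H-bonds per interior chain of a
parallel hexapeptide sheet and 12 for the antiparallel arrangement, the
package's first sanity anchor.

A topology class is assigned to a contacting sheet pair from three binary
features: parallel (classes 1–4) versus antiparallel (5–8) sheets; whether
the two sheets meet through the same face or different faces (faces are
residue-position sets determined from side-chain orientation against the
sheet normal, with a pseudo-CB along the HA bisector for glycine); and the
relative up/down orientation of facing strands, paired by position along
the shared sheet axis. Classes 9/10 (equifacial parallel) are recognized
structurally but no observed structure populates them, and the fixture
generator refuses to build them. Out-of-register sheets are flagged when
the modal H-bond registry offset differs from the in-register value (the
shift is reported as a magnitude, since its sign depends only on face
labeling); kinked LARKS chains are flagged when an interior residue lies
more than 30° (wrap-aware distance in angle space) outside the allowed
β region. Both flags ride alongside the geometric class — a pseudoclass —
and never override it.

## Interface admission

Candidate interfaces are all sheet pairs with any inter-atomic distance
below the van der Waals sum plus two probe radii. A candidate is admitted
as a zipper interface if and only if

* (i) the per-chain buried area is at least 50 Å²,
* (ii) every strand contributes at least one involved side chain,
* (iii) involved side chains average ≥ 1.5 per peptide chain, and
* (iv) a side chain counts as involved when it buries ≥ 10 Å²
  (glycine: CA burial ≥ 5 Å²).

The 1.5-side-chain average is taken jointly over the chains of both
sheets. Rejections carry the first failed criterion. Symmetry copies of
one interface are recognized by their contacting faces (residue-position
sets) plus class — individual rim residues can flicker around the 10 Å²
involvement cut between copies, so the raw involved-residue list would
be an unstable identity — and their descriptor values are arithmetic
averages with the multiplicity recorded. An interface is *partially wet*
when a solvent molecule sits between the facing surfaces inside the
footprint extent; faces fully covered by solvent never pass criterion
(i) in the first place.

## The standardized slab and the three descriptors

Descriptor values depend strongly on how much of an infinite sheet one
includes, so everything is computed on a standardized slab: three
repeating units of each sheet (one strand per unit for parallel sheets,
one strand *pair* for antiparallel ones — 3 versus 6 chains), with the
two windows chosen jointly so they face each other across the contact
region. Quantities are then read off the middle repeating unit only, so
edge distortion and intra-sheet burial cancel.

**Buried area.** With SASA_A and SASA_B the solvent-accessible areas of
each sheet's middle unit computed inside its own slab with the partner
absent, and SASA_U the same areas with both slabs present,

$$ A_b = \frac{SASA_A + SASA_B - SASA_U}{N}, \qquad
   N = \begin{cases}2 & \text{parallel}\\ 4 & \text{antiparallel,}\end{cases} $$

giving the average area one peptide chain loses to the interface. SASA
uses the rolling-probe definition (probe 1.4 Å) with a deterministic
spherical-Fibonacci point set of 960 points per atom — no randomness, so
results are reproducible to the bit — and van der Waals radii fixed to
the CCP4 AREAIMOL-style united-atom values (C 1.87, N 1.65, O 1.40,
S 1.85 Å). The per-atom accuracy against analytic sphere formulas is
better than 1 %. Absolute Ab values shift by a few Å² under a different
radii table; comparisons within one table are unaffected.

**Shape complementarity.** Contact surfaces are sampled as accessible
dots on the van der Waals spheres (720 dots/atom; a dot survives if its
probe-inflated image is solvent-accessible), with outward radial
normals. Buried dots are those within 1 Å of the partner surface; each
is paired with its nearest partner dot and scored by the opposed-normal
product weighted with exp(−w·d²), w = 0.5 Å⁻²; Sc is the median over
both directions pooled. Two matching flat walls score above 0.9 and
clashing convex surfaces markedly lower. Because the sampled surface
omits reentrant (probe-rolling) patches, absolute Sc values run lower
than molecular-surface implementations, and deeply interdigitated rigid
fixtures can even score near zero where combs slide past each other;
the package's tests therefore assert orderings and invariances, not
absolute Sc values.

**Footprint and SDi.** The footprint rectangle is a flat proxy for the
interface. Its width is the repeating-unit extent along the sheet axis
(mean inter-strand spacing × strands per unit). Its length is measured in
the projection along the sheet axis, where atoms become disks of van der
Waals radius: a probe disk of 1.4 Å approaches the groove between the two
profiles from each open end and wedges where it first touches both
profiles simultaneously (probe centres are confined between the two
sheets' centre planes, where the clearance functions are monotone); the
endpoint is the innermost facing point of the probe circle, and the
length is the distance between the two endpoints. A brute-force oracle —
dense grid search for probe positions tangent to both profiles — is kept
in the test suite. The Surface Detail Index is then

$$ SDi = \frac{A_b \times u}{\text{length} \times \text{width}}, $$

with *u* the chains per repeating unit, i.e. the one-sided buried area of
one repeating unit against its flat footprint: ≈ 1 for flat contacts,
rising towards 1.8–1.9 for cog-like interdigitation. The numerator
convention (one-sided, one repeating unit) is the one that makes SDi
nearly independent of the peptide length and reproduces the observed
1.0–1.9 range.

## Quaternary networks

Admitted interface observations form a graph over the β-sheet instances
of the expanded lattice. Degrees are evaluated on sheets whose contact
neighbourhood is complete (those containing asymmetric-unit chains): one
interface per sheet means isolated β-sandwiches (1D); interfaces on both
faces extend a catemer layer (2D); more than two — the staggered,
brick-like packings — knit a 3D network. The 2D patterns are tagged by
the lateral displacement of partners along the strand direction as a
fraction of the chain length: straight below 0.15, brick above 0.35,
tilted between; crystals with kinked (LARKS) chains are tagged
basket-weave. These thresholds are package choices (the underlying
classification is qualitative) and are exposed as arguments.

## The synthetic fixture generator

Every algorithm above is testable without downloads through a
deterministic generator of ideal peptide β-sheet crystals:

* strands are built from standard peptide bond lengths and angles at
  requested (φ, ψ) — default (−119°, +113°), the ideal β values — with
  CB placed at the L-configuration improper and ideal extended rotamers
  for A, G, V, L, I, S, N, Q, Y, W (ring orientations chosen for
  clash-free ladder stacking at 4.8 Å);
* sheets stack strands at 4.8 Å spacing; a deterministic scan over the
  strand azimuth (and registry offset for antiparallel sheets) realizes
  the inter-backbone H-bond geometry, N···O ≈ 2.8–3.2 Å in-register;
  a register shift builds out-of-register sheets;
* zippers place a transformed copy of the sheet across the x axis —
  the four rigid operations (identity and 180° rotations about x, y, z)
  realize the same-face/other-face × up/down combinatorics of classes
  1–8 — at a closest approach of 3.8 Å, with the lateral (y, z) offset
  chosen by a deterministic packing scan that maximizes buried contact
  area of interior residues (antiparallel pairs restrict the y-offset to
  a quarter spacing so facing-strand orientation stays well defined);
* the P1 cell wraps one repeating unit per sheet so lattice translations
  continue the sheets; the x-repeat realizes an isolated sandwich (1D),
  a catemer (2D) or a half-length-sheared brick packing (3D).

There is no randomness anywhere in the pipeline: identical inputs give
byte-identical outputs.

### What the fixtures do and do not show

The generator produces idealized rigid-rotamer geometry: real crystals
relax side chains, bend strands, hydrate termini and settle into packing
modes a rigid scan cannot reach. Consequences worth knowing:

* Absolute descriptor values on fixtures are indicative, not
  reproductions of any published entry; tests assert exact arithmetic
  (Eq 1, thresholds, H-bond counts) and orderings (flat < interdigitated
  SDi, Sc decay with separation), which are robust to the idealization.
* SDi on fixtures retains a residual chain-length dependence of about
  0.1 between hexa- and octapeptide alanine zippers: the bare N/C
  termini of the middle chain bury disproportionately, and the
  probe-tangency footprint carries ~0.4 Å of rim jitter from pleat
  bumps. Real structures, whose termini engage H-bond networks outside
  the dry zipper, do not show this artifact; the corresponding
  invariance check in the acceptance suite documents the gap rather
  than hiding it.
* The problem sizes used throughout the tests — sheets of 3–6 strands,
  lattices expanded to an 8 Å contact radius (five repeats along the
  sheet axis), 240–960 SASA points per atom — were chosen as the
  smallest sizes at which the middle repeating unit is fully flanked
  and descriptor values are stable to well under reporting precision.

## Numerical choices and degenerate inputs

* Areas are reported to 0.1 Å², Sc and SDi to 0.01.
* Negative Ab beyond numeric tolerance is an error (inconsistent slab);
  small negative values from sampling are clamped to zero.
* The footprint errors out when the probe passes freely between the
  sheets ("no closed interface") and when fewer than three repeating
  units are available ("insufficient lattice expansion").
* Alternative conformations resolve to the highest-occupancy conformer,
  ties to the alphabetically first altloc; sanitization is idempotent.
* Symmetry operators come from the file itself (REMARK 290 SMTRY or the
  mmCIF symop loop, converted to fractional form); a small built-in
  table covers common oligopeptide space groups when records are absent,
  and an unknown group degrades to the identity with a warning.
* Lattice translations are searched over −2..+2 cells per direction,
  which covers all contacts for small-peptide cells; a configurable cap
  guards against runaway expansions.

## Limitations

Beyond the fixture idealizations above: trigonal/hexagonal nanopore
packings are reported unclassified rather than forced into classes;
the Sc surface model is convex-only (see above); and the curated
reference-set regressions (published polymorph entries and
database-level statistics) require the corresponding PDB files, which
are not redistributed with the package — the acceptance suite states
exactly what it would check and fails visibly when they are absent.
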