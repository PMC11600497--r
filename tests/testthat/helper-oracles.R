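# Independent pure-R rolling-probe SASA (same deterministic point set as
# the compiled kernel, different code path), with a neighbour prefilter.
r_sasa <- function(xyz, radii, probe = 1.4, n_dots = 960) {
  sph <- stericzipper:::fibonacci_sphere(n_dots)
  rx <- radii + probe
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    d <- sqrt((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
                (xyz[, 3] - xyz[i, 3])^2)
    nb <- which(d < rx + rx[i] & seq_len(n) != i)
    p <- sweep(sph * rx[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, nrow(p))
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rx[j]^2
      if (!any(free)) break
    }
    4 * pi * rx[i]^2 * mean(free)
  }, numeric(1))
}

# Eq-1 buried area of a slab computed entirely through the R oracle.
r_buried_area <- function(slab, probe = 1.4) {
  A <- stericzipper:::slab_atoms(slab, "a")
  B <- stericzipper:::slab_atoms(slab, "b")
  mid_sum <- function(ctx, mid) {
    per <- r_sasa(stericzipper:::coords_of(ctx), ctx$radius, probe)
    sum(per[ctx$copy %in% mid])
  }
  list(SASA_A = mid_sum(A, slab$a_mid),
       SASA_B = mid_sum(B, slab$b_mid),
       SASA_U = mid_sum(rbind(A, B), c(slab$a_mid, slab$b_mid)),
       N = slab$N)
}
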