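# Independent oracles and shared fixtures for the test suite.
# The oracles deliberately use different constructions than the package
# internals (triple products, explicit reciprocal bases, scalar
# complex-number loops) so agreement is a real check.

ref_structs <- make_reference_structures()
fix_cands <- fixture_candidates()

# triple-product volume from explicitly constructed lattice vectors
oracle_volume <- function(lat) {
  d2r <- pi / 180
  a <- lat[1]; b <- lat[2]; cc <- lat[3]
  al <- lat[4] * d2r; be <- lat[5] * d2r; ga <- lat[6] * d2r
  va <- c(a, 0, 0)
  vb <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  vc <- c(cx, cy, sqrt(cc^2 - cx^2 - cy^2))
  cross <- c(vb[2] * vc[3] - vb[3] * vc[2],
             vb[3] * vc[1] - vb[1] * vc[3],
             vb[1] * vc[2] - vb[2] * vc[1])
  abs(sum(va * cross))
}

# d-spacing from the explicit reciprocal basis a* = (b x c)/V etc.
oracle_d_spacing <- function(hkl, lat) {
  d2r <- pi / 180
  a <- lat[1]; b <- lat[2]; cc <- lat[3]
  al <- lat[4] * d2r; be <- lat[5] * d2r; ga <- lat[6] * d2r
  va <- c(a, 0, 0)
  vb <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  vc <- c(cx, cy, sqrt(cc^2 - cx^2 - cy^2))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  V <- sum(va * cross(vb, vc))
  astar <- cross(vb, vc) / V
  bstar <- cross(vc, va) / V
  cstar <- cross(va, vb) / V
  g <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
  1 / sqrt(sum(g^2))
}

# brute-force |F|^2: scalar loop over expanded sites with complex numbers
oracle_f2 <- function(structure, hkl) {
  ex <- expand_sites(structure)
  d <- oracle_d_spacing(hkl, structure$lattice)
  s <- 1 / (2 * d)
  F <- complex(real = 0, imaginary = 0)
  for (j in seq_len(nrow(ex))) {
    f <- scattering_factor(ex$element[j], s)
    ph <- 2 * pi * sum(hkl * c(ex$x[j], ex$y[j], ex$z[j]))
    F <- F + ex$occupancy[j] * f * exp(-ex$b_iso[j] * s^2) *
      complex(real = cos(ph), imaginary = sin(ph))
  }
  Mod(F)^2
}

# random valid lattice (rejects near-degenerate angle combinations)
random_lattice <- function() {
  repeat {
    lat <- c(stats::runif(3, 3, 12), stats::runif(3, 60, 120))
    ca <- cos(lat[4] * pi / 180); cb <- cos(lat[5] * pi / 180)
    cg <- cos(lat[6] * pi / 180)
    if (1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg > 0.05) return(lat)
  }
}

# random small P1 structure with n atoms drawn from Ca/C/O
random_structure <- function(n = 3) {
  sites <- lapply(seq_len(n), function(i)
    atom_site(sample(c("Ca", "C", "O"), 1), stats::runif(3),
              occupancy = stats::runif(1, 0.5, 1),
              b_iso = stats::runif(1, 0, 2)))
  crystal_structure(random_lattice(), sites)
}

# calcite fixture reference values from an independent crystallography
# toolkit (gemmi 0.7.4 UnitCell/IT92 tables), frozen:
# five strongest reflections in descending intensity
calcite_ref <- data.frame(
  two_theta = c(29.4002, 48.5047, 47.5057, 39.4086, 43.1582),
  d = c(3.03555, 1.87532, 1.91240, 2.28463, 2.09443))

# vaterite fixture, same oracle, five strongest in descending intensity
vaterite_ref_two_theta <- c(26.7692, 24.7105, 28.8156, 30.1071, 45.4614)
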