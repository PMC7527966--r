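# Synthetic fixtures: reference crystal structures for the identified
# CaCO3 phases plus decoys, seeded noisy diffractograms, and random
# Born-stable elastic tensors. Everything is generated from constants
# declared here — no downloads, no binary data.

# Coordinate-triplet operator lists for the two space groups the fixture
# structures use (conventional hexagonal settings).
.ops_r3c_bar <- c(  # R-3c (#167), 36 operators
  "x,y,z", "-y,x-y,z", "-x+y,-x,z", "y,x,-z+1/2", "x-y,-y,-z+1/2",
  "-x,-x+y,-z+1/2", "-x,-y,-z", "y,-x+y,-z", "x-y,x,-z", "-y,-x,z+1/2",
  "-x+y,y,z+1/2", "x,x-y,z+1/2",
  "x+2/3,y+1/3,z+1/3", "-y+2/3,x-y+1/3,z+1/3", "-x+y+2/3,-x+1/3,z+1/3",
  "y+2/3,x+1/3,-z+5/6", "x-y+2/3,-y+1/3,-z+5/6", "-x+2/3,-x+y+1/3,-z+5/6",
  "-x+2/3,-y+1/3,-z+1/3", "y+2/3,-x+y+1/3,-z+1/3", "x-y+2/3,x+1/3,-z+1/3",
  "-y+2/3,-x+1/3,z+5/6", "-x+y+2/3,y+1/3,z+5/6", "x+2/3,x-y+1/3,z+5/6",
  "x+1/3,y+2/3,z+2/3", "-y+1/3,x-y+2/3,z+2/3", "-x+y+1/3,-x+2/3,z+2/3",
  "y+1/3,x+2/3,-z+1/6", "x-y+1/3,-y+2/3,-z+1/6", "-x+1/3,-x+y+2/3,-z+1/6",
  "-x+1/3,-y+2/3,-z+2/3", "y+1/3,-x+y+2/3,-z+2/3", "x-y+1/3,x+2/3,-z+2/3",
  "-y+1/3,-x+2/3,z+1/6", "-x+y+1/3,y+2/3,z+1/6", "x+1/3,x-y+2/3,z+1/6")

.ops_p6522 <- c(    # P6_5 2 2 (#179), 12 operators
  "x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2", "-x+y,-x,z+1/3",
  "y,-x+y,z+1/6", "-y,-x,-z+1/6", "-x,-x+y,-z+1/3", "-x+y,y,-z+1/2",
  "y,x,-z+2/3", "x,x-y,-z+5/6", "x-y,-y,-z")

#' Reference crystal structures for matching fixtures
#'
#' Returns four CaCO3 structures keyed by catalog id:
#' \describe{
#'   \item{mp-3953}{Calcite, conventional hexagonal R-3c cell
#'     (a = 4.9896, c = 17.061 A; Ca 6b, C 6a, O 18e with x = 0.2567 —
#'     the standard published calcite description). Expands to 30 atoms
#'     (the R-centred cell holds three 10-atom primitive cells).}
#'   \item{mp-560265}{A synthetic vaterite-type P6_5 2 2 model, Z = 18
#'     (90 atoms), cell a = 7.2, c = 26.1632 A chosen to reproduce the
#'     catalog volume 1174.591 A^3 and density 2.547 g/cc. Coordinates
#'     are plausible invented values, not a refined structure.}
#'   \item{mp-3205}{A synthetic orthorhombic (Pmmn-like) decoy, 10 atoms
#'     listed explicitly in P1, cell volume matching the catalog entry.}
#'   \item{mp-548403}{A synthetic orthorhombic (C222_1-like) decoy,
#'     likewise 10 explicit atoms at the catalog volume.}
#' }
#' Every structure expands to an atom count divisible by 5 (whole CaCO3
#' units).
#'
#' @return Named list of [crystal_structure()] objects.
#' @export
make_reference_structures <- function() {
  calcite <- crystal_structure(
    lattice = c(4.9896, 4.9896, 17.0610, 90, 90, 120),
    space_group_symbol = "R-3c",
    symmetry_ops = .ops_r3c_bar,
    sites = list(
      atom_site("Ca", c(0, 0, 0)),
      atom_site("C", c(0, 0, 0.25)),
      atom_site("O", c(0.2567, 0, 0.25))),
    formula_units = 6L)

  vaterite <- crystal_structure(
    lattice = c(7.2, 7.2, 26.163211035405542, 90, 90, 120),
    space_group_symbol = "P6_522",
    symmetry_ops = .ops_p6522,
    sites = list(
      atom_site("Ca", c(0.332, 0.072, 0.044)),          # 12-fold general
      atom_site("Ca", c(0.413, 0, 0)),                  # 6-fold (x,0,0)
      atom_site("C", c(0.345, 0.410, 0.127)),           # 12-fold general
      atom_site("C", c(0.280, 0.560, 0.25)),            # 6-fold (x,2x,1/4)
      atom_site("O", c(0.266, 0.468, 0.083)),
      atom_site("O", c(0.254, 0.270, 0.152)),
      atom_site("O", c(0.478, 0.482, 0.140)),
      atom_site("O", c(0.090, 0.380, 0.205)),
      atom_site("O", c(0.175, 0.175, 1 / 3))),          # 6-fold (x,x,1/3)
    formula_units = 18L)

  decoy_pmmn <- crystal_structure(
    lattice = c(4.02, 4.60, 5.988048886004759, 90, 90, 90),
    space_group_symbol = "Pmmn",
    symmetry_ops = "x,y,z",
    sites = list(
      atom_site("Ca", c(0, 0, 0)),
      atom_site("Ca", c(0.5, 0.5, 0.5)),
      atom_site("C", c(0.5, 0, 0.25)),
      atom_site("C", c(0, 0.5, 0.75)),
      atom_site("O", c(0.30, 0.20, 0.25)),
      atom_site("O", c(0.70, 0.20, 0.25)),
      atom_site("O", c(0.50, 0.80, 0.25)),
      atom_site("O", c(0.80, 0.70, 0.75)),
      atom_site("O", c(0.20, 0.70, 0.75)),
      atom_site("O", c(0.00, 0.30, 0.75))),
    formula_units = 2L)

  decoy_c2221 <- crystal_structure(
    lattice = c(4.25, 4.85, 5.100206185567011, 90, 90, 90),
    space_group_symbol = "C222_1",
    symmetry_ops = "x,y,z",
    sites = list(
      atom_site("Ca", c(0.25, 0.25, 0.10)),
      atom_site("Ca", c(0.75, 0.75, 0.60)),
      atom_site("C", c(0.25, 0.75, 0.40)),
      atom_site("C", c(0.75, 0.25, 0.90)),
      atom_site("O", c(0.10, 0.60, 0.45)),
      atom_site("O", c(0.40, 0.90, 0.45)),
      atom_site("O", c(0.25, 0.75, 0.15)),
      atom_site("O", c(0.60, 0.10, 0.95)),
      atom_site("O", c(0.90, 0.40, 0.95)),
      atom_site("O", c(0.75, 0.25, 0.65))),
    formula_units = 2L)

  list("mp-3953" = calcite, "mp-560265" = vaterite,
       "mp-3205" = decoy_pmmn, "mp-548403" = decoy_c2221)
}

#' Candidate catalog with fixture structures attached
#'
#' Convenience wrapper: the full 14-entry catalog with the four fixture
#' structures from [make_reference_structures()] attached; the remaining
#' entries stay structureless (the matcher skips them with a warning).
#'
#' @return List of [candidate_phase()] objects.
#' @export
fixture_candidates <- function() {
  attach_structures(load_candidate_catalog(), make_reference_structures())
}

#' Add seeded measurement noise to a diffractogram
#'
#' Adds Gaussian noise with standard deviation `sigma_frac` times the
#' maximum intensity, plus an optional polynomial background in the grid
#' coordinate, then clips negatives. Deterministic for a given seed; the
#' caller's RNG stream is left untouched.
#'
#' @param pattern A normalized [powder_pattern()].
#' @param sigma_frac Noise scale as a fraction of the maximum intensity.
#' @param background Polynomial background coefficients (constant first),
#'   evaluated in `(two_theta - scan_min)` degrees; default none.
#' @param seed Integer seed.
#' @return A [powder_pattern()] on the same grid (unnormalized).
#' @export
add_measurement_noise <- function(pattern, sigma_frac = 0.02,
                                  background = numeric(), seed = 1L) {
  stopifnot(inherits(pattern, "powder_pattern"), sigma_frac >= 0)
  y <- pattern$intensity
  m <- max(y)
  noise <- if (sigma_frac > 0)
    with_seed(seed, stats::rnorm(length(y), sd = sigma_frac * m))
  else numeric(length(y))
  bg <- numeric(length(y))
  if (length(background)) {
    u <- pattern$two_theta - min(pattern$two_theta)
    for (j in seq_along(background)) bg <- bg + background[j] * u^(j - 1)
  }
  powder_pattern(pattern$two_theta, pmax(y + noise + bg, 0),
                 wavelength = pattern$wavelength, normalized = FALSE)
}

#' Random Born-stable elastic constants
#'
#' Rejection-samples the independent constants from uniform ranges
#' (C11, C33 in \[50, 400\]; C12, C13, C44 in \[10, 150\] GPa; trigonal
#' adds C14 in \[-30, 30\]) until the Born criteria hold. Deterministic
#' per seed.
#'
#' @param symmetry `"hexagonal"` or `"trigonal"`.
#' @param seed Integer seed.
#' @return An [elastic_constants()] object.
#' @export
random_elastic_constants <- function(symmetry = c("hexagonal", "trigonal"),
                                     seed = 1L) {
  symmetry <- match.arg(symmetry)
  with_seed(seed, {
    repeat {
      c11 <- stats::runif(1, 50, 400)
      c33 <- stats::runif(1, 50, 400)
      c12 <- stats::runif(1, 10, 150)
      c13 <- stats::runif(1, 10, 150)
      c44 <- stats::runif(1, 10, 150)
      c14 <- if (symmetry == "trigonal") stats::runif(1, -30, 30) else 0
      ok <- c44 > 0 && c11 > abs(c12) && (c11 + c12) * c33 > 2 * c13^2
      if (ok)
        return(elastic_constants(c11, c12, c13, c33, c44, c14 = c14,
                                 symmetry = symmetry))
    }
  })
}

#' Write the fixture set to a directory
#'
#' Emits the four reference structures as CIF files and, for calcite and
#' vaterite, clean and seeded-noisy simulated spectra as XY text.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the noisy spectra.
#' @param sigma_frac Noise level for the noisy spectra.
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 42L, sigma_frac = 0.02) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structs <- make_reference_structures()
  files <- character()
  for (id in names(structs)) {
    f <- file.path(dir, paste0(id, ".cif"))
    write_cif(structs[[id]], f, data_name = id)
    files <- c(files, f)
  }
  for (id in c("mp-3953", "mp-560265")) {
    pat <- simulate_pattern(structs[[id]])
    f1 <- file.path(dir, paste0(id, "_clean.xy"))
    write_xy(pat, f1)
    f2 <- file.path(dir, paste0(id, "_noisy.xy"))
    write_xy(add_measurement_noise(pat, sigma_frac = sigma_frac,
                                   seed = seed), f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
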