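# Powder X-ray diffractogram simulation: Bragg geometry, structure
# factors from Cromer-Mann scattering factors, Lorentz-polarization
# correction and pseudo-Voigt profile synthesis on a uniform 2-theta grid.

#' Cu K-alpha1 wavelength (Angstrom)
#' @export
CU_KA1 <- 1.5406

# Cu K-alpha2, used only when the optional doublet is requested.
CU_KA2 <- 1.5444

# Cromer-Mann 4-Gaussian scattering-factor coefficients for neutral atoms:
# f(s) = sum_i a_i exp(-b_i s^2) + c, s = sin(theta)/lambda (1/A).
# International Tables Vol. C values for the elements this package needs.
.cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  Ca = list(a = c(8.62660, 7.38730, 1.58990, 1.02110),
            b = c(10.4421, 0.659900, 85.7484, 178.437), c = 1.37510))

#' Atomic scattering factor f(s)
#'
#' @param element Chemical symbol with packaged Cromer-Mann coefficients.
#' @param s `sin(theta)/lambda` in 1/Angstrom (scalar or vector).
#' @return f(s), electron units.
#' @export
scattering_factor <- function(element, s) {
  cm <- .cromer_mann[[element]]
  if (is.null(cm))
    stop("unsupported element (no scattering coefficients): ", element)
  s2 <- s^2
  out <- rep(cm$c, length(s))
  for (i in 1:4) out <- out + cm$a[i] * exp(-cm$b[i] * s2)
  out
}

#' Bragg diffraction angle for a d-spacing
#'
#' `2 theta = 2 asin(lambda / 2d)`, degrees. Reflections with
#' `lambda > 2d` do not diffract and return `NA` (they are dropped by the
#' pattern generator rather than raising an error).
#'
#' @param d d-spacing in Angstrom (vectorized).
#' @param wavelength Radiation wavelength in Angstrom.
#' @return 2-theta in degrees, `NA` where no reflection exists.
#' @export
bragg_two_theta <- function(d, wavelength = CU_KA1) {
  stopifnot(wavelength > 0, all(d > 0))
  ratio <- wavelength / (2 * d)
  out <- rep(NA_real_, length(d))
  ok <- ratio <= 1
  out[ok] <- 2 * asin(ratio[ok]) * 180 / pi
  out
}

#' d-spacing of reflection hkl in a general (triclinic) cell
#'
#' Computed from the reciprocal metric tensor: `1/d^2 = h* G* h`.
#'
#' @param hkl Integer triple, or an n-by-3 matrix of triples.
#' @param lattice Numeric length-6 cell parameters.
#' @return d in Angstrom (vector of length n).
#' @export
d_spacing <- function(hkl, lattice) {
  h <- if (is.matrix(hkl)) hkl else matrix(as.numeric(hkl), ncol = 3)
  if (any(rowSums(h != 0) == 0)) stop("hkl must not be the zero vector")
  A <- lattice_matrix(lattice)       # rows a, b, c
  Gstar <- solve(A %*% t(A))         # reciprocal metric tensor
  inv_d2 <- rowSums((h %*% Gstar) * h)
  1 / sqrt(inv_d2)
}

#' Lorentz-polarization factor (unpolarized beam)
#'
#' `LP = (1 + cos^2 2theta) / (sin^2 theta cos theta)`.
#'
#' @param two_theta Diffraction angle 2-theta in degrees, in (0, 180).
#' @return The LP factor (vectorized).
#' @export
lorentz_polarization <- function(two_theta) {
  if (any(two_theta <= 0 | two_theta >= 180))
    stop("two_theta must lie strictly inside (0, 180) degrees")
  th <- two_theta * pi / 360
  (1 + cos(2 * th)^2) / (sin(th)^2 * cos(th))
}

#' Squared structure-factor magnitude |F(hkl)|^2
#'
#' `F = sum_j occ_j f_j(s) exp(-B_j s^2) exp(2 pi i h.x_j)` over all
#' symmetry-expanded sites of the unit cell, `s = sin(theta)/lambda`.
#'
#' @param structure A [crystal_structure()].
#' @param hkl Integer triple or n-by-3 matrix.
#' @param s `sin(theta)/lambda` per reflection (1/A); if missing it is
#'   derived from the lattice via [d_spacing()] (`s = 1/(2d)`).
#' @param expanded Optional pre-expanded site table from [expand_sites()]
#'   (avoids re-expanding in loops).
#' @return |F|^2 per reflection, electron units squared.
#' @export
structure_factor <- function(structure, hkl, s = NULL, expanded = NULL) {
  h <- if (is.matrix(hkl)) hkl else matrix(as.numeric(hkl), ncol = 3)
  if (is.null(expanded)) expanded <- expand_sites(structure)
  if (is.null(s)) s <- 1 / (2 * d_spacing(h, structure$lattice))
  xyz <- as.matrix(expanded[, c("x", "y", "z")])
  phase <- h %*% t(xyz)                      # n_hkl x n_sites, h.x
  f <- matrix(0, nrow(h), nrow(expanded))    # per-site form factor
  for (el in unique(expanded$element)) {
    idx <- which(expanded$element == el)
    fe <- scattering_factor(el, s)           # n_hkl
    f[, idx] <- fe
  }
  damp <- exp(-outer(s^2, expanded$b_iso))   # n_hkl x n_sites
  w <- f * damp * rep(expanded$occupancy, each = nrow(h))
  re <- rowSums(w * cos(2 * pi * phase))
  im <- rowSums(w * sin(2 * pi * phase))
  re^2 + im^2
}

#' Profile and scan configuration for pattern simulation
#'
#' @param fwhm Full width at half maximum of the pseudo-Voigt peaks,
#'   degrees 2-theta.
#' @param eta Pseudo-Voigt mixing fraction in `[0, 1]` (0 = Gaussian,
#'   1 = Lorentzian).
#' @param grid_step Grid spacing, degrees.
#' @param scan_min,scan_max Scan window, degrees 2-theta.
#' @return An object of class `"profile_config"`.
#' @export
profile_config <- function(fwhm = 0.15, eta = 0.5, grid_step = 0.02,
                           scan_min = 20, scan_max = 60) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1, grid_step > 0,
            scan_min < scan_max)
  structure(list(fwhm = fwhm, eta = eta, grid_step = grid_step,
                 scan_min = scan_min, scan_max = scan_max),
            class = "profile_config")
}

#' Powder diffraction pattern container
#'
#' @param two_theta Strictly ascending 2-theta grid, degrees.
#' @param intensity Same-length non-negative intensities.
#' @param wavelength Radiation wavelength, Angstrom.
#' @param normalized Logical; if `TRUE` the maximum intensity must be 100.
#' @return An object of class `"powder_pattern"`.
#' @export
powder_pattern <- function(two_theta, intensity, wavelength = CU_KA1,
                           normalized = FALSE) {
  stopifnot(length(two_theta) == length(intensity))
  if (any(diff(two_theta) <= 0)) stop("two_theta grid must be strictly ascending")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (normalized && abs(max(intensity) - 100) > 1e-9)
    stop("normalized pattern must have max intensity 100")
  structure(list(two_theta = as.numeric(two_theta),
                 intensity = as.numeric(intensity),
                 wavelength = wavelength, normalized = normalized),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("<powder_pattern> %d points, 2theta %.2f-%.2f deg, lambda %.4f A, %s\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$wavelength,
              if (x$normalized) "normalized (max 100)" else "raw"))
  invisible(x)
}

#' @export
plot.powder_pattern <- function(x, ...) {
  graphics::plot(x$two_theta, x$intensity, type = "l",
                 xlab = expression(2 * theta ~ (degrees)),
                 ylab = "intensity", ...)
  invisible(x)
}

#' Enumerate the reflections of a structure inside the scan window
#'
#' Enumerates all hkl with a Bragg angle inside
#' `[scan_min, scan_max]`, merges symmetry-equivalent reflections (same d
#' within `1e-5` A and same |F|^2 within relative `1e-6`), accumulating
#' multiplicity, and drops systematic absences
#' (`|F|^2 < 1e-8 x max |F|^2`).
#'
#' @param structure A [crystal_structure()].
#' @param config A [profile_config()].
#' @param wavelength Wavelength in Angstrom.
#' @return A data frame with columns `h, k, l, d, two_theta, multiplicity,
#'   f2, intensity` (intensity = multiplicity x |F|^2 x LP), sorted by
#'   ascending 2-theta. Zero rows if nothing diffracts in the window.
#' @export
generate_reflections <- function(structure, config = profile_config(),
                                 wavelength = CU_KA1) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(config, "profile_config"))
  lat <- structure$lattice
  th_max <- config$scan_max * pi / 360
  th_min <- config$scan_min * pi / 360
  d_min <- wavelength / (2 * sin(th_max))
  d_max <- wavelength / (2 * sin(th_min))
  hmax <- ceiling(max(lat[1:3]) / d_min)
  rng <- -hmax:hmax
  hkl <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  d <- d_spacing(hkl, lat)
  keep <- d >= d_min & d <= d_max
  hkl <- hkl[keep, , drop = FALSE]
  d <- d[keep]
  empty <- data.frame(h = integer(), k = integer(), l = integer(),
                      d = numeric(), two_theta = numeric(),
                      multiplicity = integer(), f2 = numeric(),
                      intensity = numeric())
  if (!nrow(hkl)) return(empty)
  expanded <- expand_sites(structure)
  s <- 1 / (2 * d)
  f2 <- structure_factor(structure, hkl, s = s, expanded = expanded)
  keep <- f2 >= 1e-8 * max(f2)
  if (!any(keep)) return(empty)
  hkl <- hkl[keep, , drop = FALSE]; d <- d[keep]; f2 <- f2[keep]

  # merge equivalent reflections: group by d (<= 1e-5 A) then by f2
  ord <- order(-d, f2)
  hkl <- hkl[ord, , drop = FALSE]; d <- d[ord]; f2 <- f2[ord]
  grp_d <- cumsum(c(1, as.integer(abs(diff(d)) > 1e-5)))
  grp <- grp_d * 0
  gid <- 0
  for (g in unique(grp_d)) {
    idx <- which(grp_d == g)
    sub_f2 <- f2[idx]
    sub_grp <- cumsum(c(1, as.integer(
      abs(diff(sub_f2)) > 1e-6 * pmax(abs(sub_f2[-length(sub_f2)]), 1e-300))))
    grp[idx] <- gid + sub_grp
    gid <- gid + max(sub_grp)
  }
  first <- !duplicated(grp)
  mult <- as.integer(table(grp)[as.character(grp[first])])
  d_m <- d[first]; f2_m <- f2[first]
  hkl_m <- hkl[first, , drop = FALSE]
  tt <- bragg_two_theta(d_m, wavelength)
  out <- data.frame(h = hkl_m[, 1], k = hkl_m[, 2], l = hkl_m[, 3],
                    d = d_m, two_theta = tt, multiplicity = mult,
                    f2 = f2_m,
                    intensity = mult * f2_m * lorentz_polarization(tt))
  out <- out[order(out$two_theta), ]
  rownames(out) <- NULL
  out
}

# unit-area pseudo-Voigt centred at x0 with shared FWHM
pseudo_voigt <- function(x, x0, fwhm, eta) {
  u <- (x - x0) / fwhm
  g <- (2 / fwhm) * sqrt(log(2) / pi) * exp(-4 * log(2) * u^2)
  l <- (2 / (pi * fwhm)) / (1 + 4 * u^2)
  eta * l + (1 - eta) * g
}

#' Simulate a powder diffractogram from a crystal structure
#'
#' Each reflection from [generate_reflections()] contributes a unit-area
#' pseudo-Voigt peak at its Bragg angle, scaled by its intensity
#' (multiplicity x |F|^2 x LP); the summed profile is normalized to a
#' maximum of 100.
#'
#' @param structure A [crystal_structure()].
#' @param config A [profile_config()].
#' @param wavelength Wavelength in Angstrom (default Cu K-alpha1).
#' @param ka2 If `TRUE`, add the K-alpha2 doublet component at 1.5444 A
#'   with half weight.
#' @return A normalized [powder_pattern()] on the uniform scan grid. If no
#'   reflection falls in the window a warning is raised and the intensities
#'   are all zero (flagged unnormalized).
#' @export
#' @examples
#' calcite <- make_reference_structures()[["mp-3953"]]
#' pat <- simulate_pattern(calcite)
#' pat$two_theta[which.max(pat$intensity)]  # strongest peak near 29.4 deg
simulate_pattern <- function(structure, config = profile_config(),
                             wavelength = CU_KA1, ka2 = FALSE) {
  grid <- seq(config$scan_min, config$scan_max, by = config$grid_step)
  comp <- if (ka2) list(c(wavelength, 1), c(CU_KA2, 0.5))
          else list(c(wavelength, 1))
  y <- numeric(length(grid))
  n_refl <- 0L
  for (cw in comp) {
    refl <- generate_reflections(structure, config, wavelength = cw[1])
    n_refl <- n_refl + nrow(refl)
    for (i in seq_len(nrow(refl)))
      y <- y + cw[2] * refl$intensity[i] *
        pseudo_voigt(grid, refl$two_theta[i], config$fwhm, config$eta)
  }
  if (n_refl == 0L || max(y) <= 0) {
    warning("no reflections in the scan window; returning an all-zero pattern")
    return(powder_pattern(grid, numeric(length(grid)),
                          wavelength = wavelength, normalized = FALSE))
  }
  powder_pattern(grid, y / max(y) * 100, wavelength = wavelength,
                 normalized = TRUE)
}

#' Normalize a pattern to a maximum intensity of 100
#'
#' Linear scaling; idempotent and invariant to any positive prefactor.
#'
#' @param pattern A [powder_pattern()].
#' @return The normalized pattern.
#' @export
normalize_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "powder_pattern"))
  m <- max(pattern$intensity)
  if (m <= 0) stop("cannot normalize an all-zero pattern")
  powder_pattern(pattern$two_theta, pattern$intensity / m * 100,
                 wavelength = pattern$wavelength, normalized = TRUE)
}

#' Read a two-column XY diffractogram
#'
#' Whitespace-separated 2-theta / intensity text; `#` starts a comment.
#'
#' @param path Input file path.
#' @param wavelength Wavelength to record on the pattern (Angstrom).
#' @return A [powder_pattern()] (unnormalized).
#' @export
read_xy <- function(path, wavelength = CU_KA1) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("two_theta", "intensity"))
  ord <- order(tab$two_theta)
  powder_pattern(tab$two_theta[ord], pmax(tab$intensity[ord], 0),
                 wavelength = wavelength, normalized = FALSE)
}

#' Write a pattern as two-column XY text
#'
#' @param pattern A [powder_pattern()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(pattern, path) {
  stopifnot(inherits(pattern, "powder_pattern"))
  hdr <- sprintf("# powder pattern: wavelength %.4f A, %s",
                 pattern$wavelength,
                 if (pattern$normalized) "normalized (max 100)" else "raw counts")
  body <- sprintf("%.6f %.8f", pattern$two_theta, pattern$intensity)
  writeLines(c(hdr, "# two_theta_deg intensity", body), path)
  invisible(path)
}
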