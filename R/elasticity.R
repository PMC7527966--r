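# Voigt-Reuss-Hill averaging of hexagonal/trigonal single-crystal elastic
# constants into polycrystalline moduli, plus the Poisson-ratio ductility
# classification.

#' Single-crystal elastic constants (hexagonal or trigonal)
#'
#' Hexagonal crystals have five independent constants C11, C12, C13, C33,
#' C44 (with C66 = (C11 - C12)/2); trigonal crystals add C14 (and C15 for
#' the lower-symmetry classes, stored but unused by the averaging, which
#' treats trigonal tensors with the hexagonal-form expressions).
#'
#' Born stability is enforced: `C44 > 0`, `C11 > |C12|`, and
#' `(C11 + C12) C33 > 2 C13^2`.
#'
#' @param c11,c12,c13,c33,c44 Elastic constants, GPa.
#' @param c14,c15 Trigonal constants, GPa (default 0).
#' @param symmetry `"hexagonal"` or `"trigonal"`.
#' @return An object of class `"elastic_constants"` with derived `c66`.
#' @export
elastic_constants <- function(c11, c12, c13, c33, c44, c14 = 0, c15 = 0,
                              symmetry = c("hexagonal", "trigonal")) {
  symmetry <- match.arg(symmetry)
  if (!(c44 > 0))
    stop("Born stability violated: C44 > 0 required (C44 = ", c44, ")")
  if (!(c11 > abs(c12)))
    stop("Born stability violated: C11 > |C12| required")
  if (!((c11 + c12) * c33 > 2 * c13^2))
    stop("Born stability violated: (C11 + C12) C33 > 2 C13^2 required")
  structure(list(symmetry = symmetry, c11 = c11, c12 = c12, c13 = c13,
                 c33 = c33, c44 = c44, c14 = c14, c15 = c15,
                 c66 = (c11 - c12) / 2),
            class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf("<elastic_constants> %s: C11=%.2f C12=%.2f C13=%.2f C33=%.2f C44=%.2f C66=%.2f",
              x$symmetry, x$c11, x$c12, x$c13, x$c33, x$c44, x$c66))
  if (x$symmetry == "trigonal") cat(sprintf(" C14=%.2f", x$c14))
  cat(" GPa\n")
  invisible(x)
}

#' Voigt (uniform-strain) bulk and shear moduli
#'
#' Standard hexagonal forms:
#' `B_V = [2(C11 + C12) + 4 C13 + C33] / 9` and
#' `G_V = [7 C11 - 5 C12 + 12 C44 + 2 C33 - 4 C13] / 30`.
#' `variant = "as_printed"` switches the bulk modulus to the literal
#' published variant `[2(C11 + C12) + C33 + C13] / 9`.
#'
#' @param c An [elastic_constants()] object.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return Named numeric `c(b_v, g_v)`, GPa.
#' @export
voigt_moduli <- function(c, variant = c("standard", "as_printed")) {
  stopifnot(inherits(c, "elastic_constants"))
  variant <- match.arg(variant)
  b_v <- if (variant == "standard")
    (2 * (c$c11 + c$c12) + 4 * c$c13 + c$c33) / 9
  else
    (2 * (c$c11 + c$c12) + c$c33 + c$c13) / 9
  g_v <- (7 * c$c11 - 5 * c$c12 + 12 * c$c44 + 2 * c$c33 - 4 * c$c13) / 30
  c(b_v = b_v, g_v = g_v)
}

#' Reuss (uniform-stress) bulk and shear moduli
#'
#' With `Csq = (C11 + C12) C33 - 2 C13^2`:
#' `B_R = Csq / (C11 + C12 + 2 C33 - 4 C13)` (standard;
#' `variant = "as_printed"` uses the literal published denominator
#' `C11 + C12 + C33 - C13`) and
#' `G_R = 5 Csq C44 C66 / [6 B_V C44 C66 + 2 Csq (C44 + C66)]`.
#'
#' @inheritParams voigt_moduli
#' @return Named numeric `c(b_r, g_r)`, GPa.
#' @export
reuss_moduli <- function(c, variant = c("standard", "as_printed")) {
  stopifnot(inherits(c, "elastic_constants"))
  variant <- match.arg(variant)
  csq <- (c$c11 + c$c12) * c$c33 - 2 * c$c13^2
  if (csq <= 0)
    stop("Born stability violated: (C11 + C12) C33 - 2 C13^2 must be > 0")
  den_b <- if (variant == "standard")
    c$c11 + c$c12 + 2 * c$c33 - 4 * c$c13
  else
    c$c11 + c$c12 + c$c33 - c$c13
  if (abs(den_b) < 1e-12) stop("degenerate tensor: zero bulk denominator")
  b_v <- voigt_moduli(c, variant = "standard")[["b_v"]]
  den_g <- 6 * b_v * c$c44 * c$c66 + 2 * csq * (c$c44 + c$c66)
  if (abs(den_g) < 1e-12) stop("degenerate tensor: zero shear denominator")
  c(b_r = csq / den_b,
    g_r = 5 * csq * c$c44 * c$c66 / den_g)
}

#' Hill average of the Voigt and Reuss bounds
#'
#' @param voigt,reuss Positive moduli, GPa.
#' @return Their arithmetic mean.
#' @export
hill_average <- function(voigt, reuss) {
  stopifnot(voigt > 0, reuss > 0)
  (voigt + reuss) / 2
}

#' Young's modulus and Poisson's ratio from bulk and shear moduli
#'
#' `E = 9 B G / (3 B + G)` and `nu = (3 B - 2 G) / (2 (3 B + G))`.
#'
#' @param b,g Bulk and shear moduli, GPa (vectorized).
#' @return A list with numeric `e` (GPa) and `nu` (dimensionless).
#' @export
young_and_poisson <- function(b, g) {
  stopifnot(all(b > 0), all(g > 0))
  list(e = 9 * b * g / (3 * b + g),
       nu = (3 * b - 2 * g) / (2 * (3 * b + g)))
}

#' Ductility classification from Poisson's ratio
#'
#' The critical value is 0.26: below it a material is predicted brittle,
#' at or above it ductile.
#'
#' @param nu Poisson's ratio in (-1, 0.5) (vectorized).
#' @return `"brittle"` or `"ductile"` per element.
#' @export
classify_ductility <- function(nu) {
  if (any(nu <= -1 | nu >= 0.5))
    stop("Poisson's ratio must lie in (-1, 0.5)")
  ifelse(nu < 0.26, "brittle", "ductile")
}

# shared table builder: Voigt/Reuss/Hill rows + per-column average
vrh_build <- function(b_v, g_v, b_r, g_r, variant = "standard") {
  b_h <- hill_average(b_v, b_r)
  g_h <- hill_average(g_v, g_r)
  b <- c(b_v, b_r, b_h)
  g <- c(g_v, g_r, g_h)
  en <- young_and_poisson(b, g)
  tab <- data.frame(scheme = c("Voigt", "Reuss", "Hill"),
                    bulk = b, young = en$e, shear = g, poisson = en$nu,
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(scheme = "Average",
                               bulk = mean(tab$bulk), young = mean(tab$young),
                               shear = mean(tab$shear),
                               poisson = mean(tab$poisson)))
  structure(list(table = tab,
                 ductility = classify_ductility(en$nu[3]),  # Hill nu
                 variant = variant),
            class = "vrh")
}

#' Voigt-Reuss-Hill report for a single-crystal elastic tensor
#'
#' Computes the Voigt and Reuss bulk/shear bounds, their Hill averages,
#' Young's modulus and Poisson's ratio per averaging scheme, the
#' per-column mean of the three schemes ("Average" row), and the
#' ductility class from the Hill Poisson's ratio.
#'
#' @param c An [elastic_constants()] object.
#' @param variant `"standard"` (default) or `"as_printed"`; see
#'   [voigt_moduli()] and [reuss_moduli()].
#' @return An object of class `"vrh"` with a four-row `$table`
#'   (Voigt/Reuss/Hill/Average x bulk/young/shear/poisson, full
#'   precision) and `$ductility`.
#' @export
#' @examples
#' cc <- elastic_constants(c11 = 150, c12 = 60, c13 = 55, c33 = 85,
#'                         c44 = 34, symmetry = "trigonal")
#' vrh(cc)
vrh <- function(c, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  v <- voigt_moduli(c, variant)
  r <- reuss_moduli(c, variant)
  out <- vrh_build(v[["b_v"]], v[["g_v"]], r[["b_r"]], r[["g_r"]], variant)
  out$constants <- c
  out
}

#' Voigt-Reuss-Hill report from precomputed Voigt/Reuss bounds
#'
#' Builds the same table as [vrh()] when only the polycrystalline Voigt
#' and Reuss bulk/shear moduli are known (e.g. published values whose
#' underlying single-crystal constants are not available).
#'
#' @param b_v,g_v,b_r,g_r Voigt and Reuss bulk/shear moduli, GPa.
#' @return An object of class `"vrh"`.
#' @export
#' @examples
#' # trigonal biogenic calcite, from its published Voigt/Reuss bounds
#' vrh_from_bounds(b_v = 81.32, g_v = 37.188, b_r = 74.309, g_r = 30.103)
vrh_from_bounds <- function(b_v, g_v, b_r, g_r) {
  stopifnot(b_v > 0, g_v > 0, b_r > 0, g_r > 0)
  vrh_build(b_v, g_v, b_r, g_r)
}

#' @export
print.vrh <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$bulk <- round(tab$bulk, digits)
  tab$young <- round(tab$young, digits)
  tab$shear <- round(tab$shear, digits)
  tab$poisson <- round(tab$poisson, digits)
  names(tab) <- c("Averaging scheme", "Bulk modulus (GPa)",
                  "Young's modulus (GPa)", "Shear modulus (GPa)",
                  "Poisson's ratio")
  cat("Voigt-Reuss-Hill polycrystalline moduli:\n")
  print(tab, row.names = FALSE)
  cat(sprintf("Ductility (Hill nu %s 0.26): %s\n",
              if (x$table$poisson[3] < 0.26) "<" else ">=", x$ductility))
  invisible(x)
}

#' @export
summary.vrh <- function(object, ...) {
  print(object, ...)
  invisible(object$table)
}
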