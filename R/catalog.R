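# Candidate catalog of CaCO3 polymorphs: Materials Project-style entries
# (id, space group, per-atom formation energy, band gap, cell volume, atom
# count, density), transcribed verbatim so the catalog is usable offline.

.catalog_table <- function() {
  data.frame(
    materials_id = c("mp-3953", "mp-556235", "mp-561412", "mp-560265",
                     "mp-1194399", "mp-1197939", "mp-553939", "mp-1079918",
                     "mp-4626", "mp-1197230", "mp-3205", "mp-548403",
                     "mp-641635", "mp-696740"),
    space_group = c("R3c", "P2_1/c", "C2", "P6_522", "C2/c", "P1", "Pnma",
                    "P1", "Pnma", "P1", "Pmmn", "C222_1", "Pnma", "C2/c"),
    formation_energy = c(-2.707, -2.705, -2.700, -2.699, -2.699, -2.698,
                         -2.694, -2.691, -2.683, -2.683, -2.537, -2.395,
                         -1.338, -0.689),
    band_gap = c(5.002, 4.960, 4.958, 4.944, 4.910, 4.943, 4.700, 4.849,
                 4.171, 4.940, 4.257, 5.719, 1.185, 1.435),
    volume = c(127.17, 253.066, 191.628, 1174.591, 389.315, 1170.318,
               258.226, 124.855, 234.244, 591.983, 110.731, 105.128,
               306.458, 118.88),
    n_sites = c(10L, 20L, 15L, 90L, 30L, 90L, 20L, 10L, 20L, 50L, 10L,
                10L, 20L, 10L),
    density = c(2.614, 2.627, 2.602, 2.547, 2.561, 2.556, 2.574, 2.662,
                2.838, 2.807, 3.002, 3.162, 2.169, 2.796),
    stringsAsFactors = FALSE)
}

#' One catalog entry for a candidate CaCO3 polymorph
#'
#' @param materials_id Catalog identifier (e.g. `"mp-3953"`).
#' @param space_group Space-group label.
#' @param formation_energy Formation energy in eV per atom; more negative
#'   means more stable.
#' @param band_gap Band gap in eV (carried but unused by the matcher).
#' @param volume Unit-cell volume, cubic Angstrom.
#' @param n_sites Atoms per unit cell; must be divisible by 5 for CaCO3.
#' @param density Mass density, g/cm^3; checked against the value
#'   recomputed from `volume` and `n_sites` to within 0.002 g/cc.
#' @param structure Optional [crystal_structure()] used for pattern
#'   simulation.
#' @return An object of class `"candidate_phase"`.
#' @export
candidate_phase <- function(materials_id, space_group, formation_energy,
                            band_gap = NA, volume, n_sites, density,
                            structure = NULL) {
  if (n_sites %% 5L != 0L)
    stop("stoichiometry error: n_sites must be divisible by 5 for CaCO3")
  rho <- mass_density(volume, n_sites, "CaCO3")
  if (abs(rho - density) > 0.002)
    stop(sprintf(
      "density %.3f g/cc inconsistent with volume/n_sites (recomputed %.4f)",
      density, rho))
  if (!is.null(structure)) stopifnot(inherits(structure, "crystal_structure"))
  structure(
    list(materials_id = materials_id, space_group = space_group,
         formation_energy = formation_energy, band_gap = band_gap,
         volume = volume, n_sites = n_sites, density = density,
         structure = structure),
    class = "candidate_phase")
}

#' Load the packaged candidate catalog of CaCO3 polymorphs
#'
#' Fourteen entries covering every CaCO3 crystal structure in the source
#' catalog. Entries carry no atomic coordinates; attach structures with
#' [attach_structures()] before pattern simulation.
#'
#' @return A list of [candidate_phase()] objects, in catalog order
#'   (ascending formation energy).
#' @export
#' @examples
#' cat14 <- load_candidate_catalog()
#' length(cat14)                       # 14
#' cat14[[1]]$materials_id             # "mp-3953", the most stable phase
load_candidate_catalog <- function() {
  tab <- .catalog_table()
  lapply(seq_len(nrow(tab)), function(i)
    candidate_phase(tab$materials_id[i], tab$space_group[i],
                    tab$formation_energy[i], tab$band_gap[i],
                    tab$volume[i], tab$n_sites[i], tab$density[i]))
}

#' Attach crystal structures to catalog entries
#'
#' @param candidates List of [candidate_phase()] objects.
#' @param structures Named list of [crystal_structure()] objects, names
#'   matching `materials_id`s. Entries without a match are left without a
#'   structure (the matcher skips them with a warning).
#' @return The candidate list with structures filled in.
#' @export
attach_structures <- function(candidates, structures) {
  stopifnot(is.list(structures), !is.null(names(structures)))
  lapply(candidates, function(cand) {
    s <- structures[[cand$materials_id]]
    if (!is.null(s)) cand$structure <- s
    cand
  })
}

#' @export
print.candidate_phase <- function(x, ...) {
  cat(sprintf("<candidate_phase> %s (%s)  Ef = %.3f eV/atom  V = %.3f A^3  %d sites  rho = %.3f g/cc  structure: %s\n",
              x$materials_id, x$space_group, x$formation_energy, x$volume,
              x$n_sites, x$density,
              if (is.null(x$structure)) "absent" else "attached"))
  invisible(x)
}

#' Catalog as a data frame
#'
#' @return The packaged catalog as a data frame (one row per entry).
#' @export
catalog_table <- function() .catalog_table()
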