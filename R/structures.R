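# Crystal-structure data model, CIF ingestion and stoichiometry/density
# utilities for the CaCO3 candidate catalog.

#' Atomic site in the asymmetric unit
#'
#' @param element Chemical symbol (e.g. `"Ca"`, `"C"`, `"O"`).
#' @param frac_coords Numeric length-3 fractional coordinates; reduced into
#'   `[0, 1)` on construction.
#' @param occupancy Site occupancy in `(0, 1]`.
#' @param b_iso Isotropic displacement parameter B (A^2); damps scattering
#'   as `exp(-B s^2)` with `s = sin(theta)/lambda`.
#' @return An object of class `"atom_site"`.
#' @export
atom_site <- function(element, frac_coords, occupancy = 1, b_iso = 0) {
  stopifnot(is.character(element), length(element) == 1L,
            is.numeric(frac_coords), length(frac_coords) == 3L)
  if (!is.finite(occupancy) || occupancy <= 0 || occupancy > 1)
    stop("occupancy must lie in (0, 1], got ", occupancy)
  if (b_iso < 0) stop("b_iso must be >= 0")
  structure(
    list(element = element,
         frac_coords = unname(as.numeric(frac_coords)) %% 1,
         occupancy = unname(occupancy),
         b_iso = unname(b_iso)),
    class = "atom_site")
}

#' Crystal structure (lattice + symmetry + asymmetric unit)
#'
#' @param lattice Numeric length-6: `a, b, c` in Angstrom and
#'   `alpha, beta, gamma` in degrees.
#' @param sites List of [atom_site()] objects (the asymmetric unit).
#' @param space_group_symbol Text label, e.g. `"R-3c"`; informational only —
#'   symmetry comes from `symmetry_ops`.
#' @param symmetry_ops Character vector of coordinate-triplet operator
#'   strings such as `"-y,x-y,z+1/3"`. Defaults to the identity (P1).
#' @param formula_units Number of formula units in the cell, or `NA`.
#' @return An object of class `"crystal_structure"`.
#' @export
crystal_structure <- function(lattice, sites, space_group_symbol = "P1",
                              symmetry_ops = "x,y,z", formula_units = NA) {
  lattice <- as.numeric(lattice)
  if (length(lattice) != 6L || any(!is.finite(lattice)))
    stop("lattice must be six finite numbers: a, b, c, alpha, beta, gamma")
  names(lattice) <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (any(lattice[1:3] <= 0)) stop("invalid lattice: cell lengths must be > 0")
  if (any(lattice[4:6] <= 0) || any(lattice[4:6] >= 180))
    stop("invalid lattice: cell angles must lie in (0, 180) degrees")
  if (!length(sites)) stop("at least one atom site is required")
  stopifnot(all(vapply(sites, inherits, logical(1), "atom_site")))
  ops <- lapply(symmetry_ops, parse_symop)  # fail early on bad operators
  obj <- structure(
    list(lattice = lattice,
         space_group_symbol = space_group_symbol,
         symmetry_ops = symmetry_ops,
         ops = ops,
         sites = sites,
         formula_units = formula_units),
    class = "crystal_structure")
  if (cell_volume(obj) <= 0) stop("invalid lattice: non-positive cell volume")
  obj
}

#' @export
print.crystal_structure <- function(x, ...) {
  lat <- x$lattice
  cat(sprintf("<crystal_structure> %s\n", x$space_group_symbol))
  cat(sprintf("  a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              lat["a"], lat["b"], lat["c"], lat["alpha"], lat["beta"], lat["gamma"]))
  cat(sprintf("  V = %.3f A^3, %d asymmetric site(s), %d symmetry op(s)\n",
              cell_volume(x), length(x$sites), length(x$ops)))
  invisible(x)
}

#' Unit-cell volume from the lattice parameters
#'
#' `V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param x A `crystal_structure` or a numeric length-6 lattice.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(x) {
  lat <- if (inherits(x, "crystal_structure")) x$lattice else as.numeric(x)
  ca <- cos(lat[4] * pi / 180); cb <- cos(lat[5] * pi / 180)
  cg <- cos(lat[6] * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) stop("invalid lattice: degenerate cell (volume <= 0)")
  unname(lat[1] * lat[2] * lat[3] * sqrt(arg))
}

#' Cartesian lattice-vector matrix (rows a, b, c)
#'
#' Standard crystallographic frame: a along x, b in the xy plane.
#' @param lattice Numeric length-6 cell parameters.
#' @return 3x3 matrix with lattice vectors as rows (Angstrom).
#' @export
lattice_matrix <- function(lattice) {
  lat <- as.numeric(lattice)
  a <- lat[1]; b <- lat[2]; cc <- lat[3]
  al <- lat[4] * pi / 180; be <- lat[5] * pi / 180; ga <- lat[6] * pi / 180
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- cc^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("invalid lattice: degenerate cell")
  rbind(c(a, 0, 0),
        c(b * cos(ga), b * sin(ga), 0),
        c(cx, cy, sqrt(cz2)))
}

# Parse a coordinate-triplet symmetry operator string ("-y,x-y,z+1/3")
# into a 3x3 rotation matrix and a translation vector.
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", s), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("cannot parse symmetry operator string: '", s, "'")
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms: x/y/z with coefficient, fractions, decimals
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    if (!length(toks) || paste(toks, collapse = "") != expr)
      stop("cannot parse symmetry operator string: '", s, "'")
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (grepl("^[0-9.]*\\*?[xyz]$", body)) {
        coef <- sub("\\*?[xyz]$", "", body)
        coef <- if (nzchar(coef)) as.numeric(coef) else 1
        ax <- match(substr(body, nchar(body), nchar(body)), c("x", "y", "z"))
        R[i, ax] <- R[i, ax] + sign * coef
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator string: '", s, "'")
      }
    }
  }
  list(R = R, t = t %% 1)
}

#' Expand the asymmetric unit through the symmetry operators
#'
#' Applies every operator to every site, reduces coordinates into `[0, 1)`
#' and merges duplicates closer than `tol` in fractional coordinates on all
#' three axes (with wrap-around).
#'
#' @param structure A `crystal_structure`.
#' @param tol Merge tolerance in fractional coordinates (default `1e-3`).
#' @return A data frame with columns `element, x, y, z, occupancy, b_iso`,
#'   one row per atom in the full unit cell.
#' @export
expand_sites <- function(structure, tol = 1e-3) {
  stopifnot(inherits(structure, "crystal_structure"))
  rows <- vector("list", length(structure$sites))
  for (k in seq_along(structure$sites)) {
    site <- structure$sites[[k]]
    pos <- vapply(structure$ops,
                  function(op) (op$R %*% site$frac_coords + op$t) %% 1,
                  numeric(3))
    pos <- t(pos)  # n_ops x 3
    dimnames(pos) <- NULL
    keep <- rep(TRUE, nrow(pos))
    for (i in seq_len(nrow(pos))) {
      if (!keep[i]) next
      if (i < nrow(pos)) {
        d <- abs(sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ]))
        d <- pmin(d, 1 - d)
        dup <- which(apply(d < tol, 1, all))
        keep[i + dup] <- FALSE
      }
    }
    pos <- pos[keep, , drop = FALSE]
    rows[[k]] <- data.frame(element = site$element,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            occupancy = site$occupancy, b_iso = site$b_iso)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Molar masses (g/mol), IUPAC 2021 abridged values.
.molar_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974,
                 S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078)

.avogadro <- 6.02214076e23

# "CaCO3" -> c(Ca = 1, C = 1, O = 3)
parse_formula <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula)
    stop("cannot parse chemical formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.molar_mass))
  if (length(unknown))
    stop("no molar mass tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  sum(counts * .molar_mass[names(counts)])
}

#' Mass density of a crystal from cell volume and atom count
#'
#' `rho = n_fu * M / N_A / (V * 1e-24 cm^3)` with `n_fu` the number of
#' formula units implied by `n_sites`.
#'
#' @param volume Unit-cell volume in cubic Angstrom.
#' @param n_sites Total number of atoms in the cell; must be divisible by
#'   the atoms-per-formula of `composition`.
#' @param composition Chemical formula, default `"CaCO3"` (5 atoms/formula).
#' @return Density in g/cm^3.
#' @export
#' @examples
#' mass_density(127.17, 10)  # calcite-type cell, ~2.614 g/cc
mass_density <- function(volume, n_sites, composition = "CaCO3") {
  if (volume <= 0) stop("volume must be > 0")
  counts <- parse_formula(composition)
  apfu <- sum(counts)
  if (n_sites %% apfu != 0)
    stop("stoichiometry error: n_sites (", n_sites,
         ") not divisible by atoms per formula (", apfu, ")")
  n_fu <- n_sites / apfu
  n_fu * formula_mass(composition) / .avogadro / (volume * 1e-24)
}

#' Read a crystal structure from a CIF file (scoped dialect)
#'
#' Supports one data block with the core tags: `_cell_length_{a,b,c}`,
#' `_cell_angle_{alpha,beta,gamma}`, an optional space-group name, an
#' optional symmetry-operator loop (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`) and an atom-site loop with
#' fractional coordinates. Files without an operator loop are treated
#' as P1.
#'
#' @param path Path to a CIF file.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  cell <- c(a = NA, b = NA, c = NA, alpha = NA, beta = NA, gamma = NA)
  tagmap <- c("_cell_length_a" = "a", "_cell_length_b" = "b",
              "_cell_length_c" = "c", "_cell_angle_alpha" = "alpha",
              "_cell_angle_beta" = "beta", "_cell_angle_gamma" = "gamma")
  sg <- "P1"
  ops <- NULL
  site_rows <- NULL

  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^data_", ln)) { i <- i + 1L; next }
    if (tolower(ln) == "loop_") {
      # collect header tags then body rows
      hdr <- character()
      i <- i + 1L
      while (i <= n && startsWith(lines[i], "_")) {
        hdr <- c(hdr, strsplit(lines[i], "[[:space:]]+")[[1]][1])
        i <- i + 1L
      }
      body <- character()
      while (i <= n && !startsWith(lines[i], "_") &&
             tolower(lines[i]) != "loop_" && !grepl("^data_", lines[i])) {
        body <- c(body, lines[i])
        i <- i + 1L
      }
      lhdr <- tolower(hdr)
      if (any(lhdr %in% c("_symmetry_equiv_pos_as_xyz",
                          "_space_group_symop_operation_xyz"))) {
        opcol <- which(lhdr %in% c("_symmetry_equiv_pos_as_xyz",
                                   "_space_group_symop_operation_xyz"))
        vals <- lapply(body, cif_fields)
        ops <- vapply(vals, function(v) v[[opcol]], character(1))
      } else if (any(grepl("^_atom_site_", lhdr))) {
        vals <- lapply(body, cif_fields)
        bad <- vapply(vals, length, integer(1)) != length(hdr)
        if (any(bad))
          stop("CIF format error: atom-site row has wrong field count: '",
               body[which(bad)[1]], "'")
        m <- do.call(rbind, vals)
        colnames(m) <- lhdr
        site_rows <- as.data.frame(m, stringsAsFactors = FALSE)
      }
      next
    }
    if (startsWith(ln, "_")) {
      kv <- strsplit(ln, "[[:space:]]+")[[1]]
      tag <- tolower(kv[1])
      val <- if (length(kv) > 1) paste(kv[-1], collapse = " ") else ""
      if (tag %in% names(tagmap)) {
        cell[tagmap[[tag]]] <- cif_number(val)
      } else if (tag %in% c("_symmetry_space_group_name_h-m",
                            "_space_group_name_h-m_alt")) {
        sg <- gsub("^['\"]|['\"]$", "", val)
      }
    }
    i <- i + 1L
  }

  missing_tag <- names(tagmap)[is.na(cell[tagmap])]
  if (length(missing_tag))
    stop("CIF format error: missing cell parameter tag ", missing_tag[1])
  if (is.null(site_rows) || !nrow(site_rows))
    stop("CIF format error: no atom-site loop found")

  needed <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (!all(needed %in% colnames(site_rows)))
    stop("CIF format error: atom-site loop lacks fractional coordinates")
  elcol <- intersect(c("_atom_site_type_symbol", "_atom_site_label"),
                     colnames(site_rows))[1]
  if (is.na(elcol))
    stop("CIF format error: atom-site loop lacks an element column")
  occ <- if ("_atom_site_occupancy" %in% colnames(site_rows))
    vapply(site_rows[["_atom_site_occupancy"]], cif_number, numeric(1))
  else rep(1, nrow(site_rows))
  biso <- if ("_atom_site_b_iso_or_equiv" %in% colnames(site_rows))
    vapply(site_rows[["_atom_site_b_iso_or_equiv"]], cif_number, numeric(1))
  else rep(0, nrow(site_rows))

  sites <- lapply(seq_len(nrow(site_rows)), function(j) {
    el <- sub("[0-9+-]*$", "", site_rows[[elcol]][j])
    atom_site(el,
              c(cif_number(site_rows[["_atom_site_fract_x"]][j]),
                cif_number(site_rows[["_atom_site_fract_y"]][j]),
                cif_number(site_rows[["_atom_site_fract_z"]][j])),
              occupancy = occ[j], b_iso = biso[j])
  })
  crystal_structure(cell, sites, space_group_symbol = sg,
                    symmetry_ops = if (is.null(ops)) "x,y,z" else ops)
}

# split a CIF body row into fields, honouring single/double quotes
cif_fields <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)
  f <- regmatches(line, m)[[1]]
  gsub("^['\"]|['\"]$", "", f)
}

# numeric CIF value, stripping an "(esd)" suffix
cif_number <- function(s) {
  v <- suppressWarnings(as.numeric(sub("\\(.*\\)$", "", s)))
  if (is.na(v)) stop("CIF format error: expected a number, got '", s, "'")
  v
}

#' Write a crystal structure to a CIF file (scoped dialect)
#'
#' Emits the cell parameters, the space-group label, the full
#' symmetry-operator loop and the asymmetric-unit atom-site loop, in the
#' same dialect [read_cif()] consumes, so structures round-trip.
#'
#' @param structure A `crystal_structure`.
#' @param path Output file path.
#' @param data_name CIF data-block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path, data_name = "structure") {
  stopifnot(inherits(structure, "crystal_structure"))
  lat <- structure$lattice
  out <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_-]", "_", data_name)),
    sprintf("_cell_length_a    %.6f", lat["a"]),
    sprintf("_cell_length_b    %.6f", lat["b"]),
    sprintf("_cell_length_c    %.6f", lat["c"]),
    sprintf("_cell_angle_alpha %.6f", lat["alpha"]),
    sprintf("_cell_angle_beta  %.6f", lat["beta"]),
    sprintf("_cell_angle_gamma %.6f", lat["gamma"]),
    sprintf("_symmetry_space_group_name_H-M '%s'", structure$space_group_symbol),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    sprintf("'%s'", structure$symmetry_ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_B_iso_or_equiv",
    vapply(seq_along(structure$sites), function(j) {
      s <- structure$sites[[j]]
      sprintf("%s%d %s %.9f %.9f %.9f %.6f %.6f", s$element, j, s$element,
              s$frac_coords[1], s$frac_coords[2], s$frac_coords[3],
              s$occupancy, s$b_iso)
    }, character(1)))
  writeLines(out, path)
  invisible(path)
}
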