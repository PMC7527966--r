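---
title: "Identifying biogenic CaCO3 phases from powder XRD and predicting their elastic moduli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying biogenic CaCO3 phases from powder XRD and predicting their elastic moduli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcphase)
```

## The problem

Bacteria that raise the pH of their medium can precipitate calcium
carbonate on their cell surfaces (microbially induced calcium carbonate
precipitation, MICP). The polymorph that forms — stable trigonal
calcite, metastable hexagonal vaterite, or something rarer — depends on
the calcium source and growth conditions, and it matters: calcite is the
durable phase that strengthens cementitious materials, while vaterite
tends to convert to calcite over time. A powder X-ray diffractogram of
the precipitate carries the fingerprint of its phase, but biogenic
powders are noisy, weakly crystalline samples, and eyeballing peak lists
against reference cards is subjective. `calcphase` implements a
quantitative pipeline: simulate candidate patterns from crystal
structures, fit smooth spectral models to both sides, and rank
candidates by spectral misfit weighted by thermodynamic plausibility.

## Pattern simulation

A candidate is a `crystal_structure`: cell parameters, explicit
symmetry operators (coordinate triplets), and the asymmetric unit. For
every reflection *hkl* inside the scan window the simulator computes

* the d-spacing from the reciprocal metric tensor of the general
  triclinic cell, and the Bragg angle 2θ = 2 asin(λ/2d);
* the squared structure factor |F|² with
  F = Σⱼ occⱼ fⱼ(s) exp(−Bⱼs²) exp(2πi h·xⱼ) over all
  symmetry-expanded sites, s = sin θ/λ, using 4-term Cromer–Mann
  scattering factors for neutral atoms (Ca, C, O and a few others are
  tabulated);
* the unpolarized-beam Lorentz–polarization correction
  LP = (1 + cos² 2θ)/(sin² θ cos θ).

Symmetry-equivalent reflections (equal d within 10⁻⁵ Å and equal |F|²
within relative 10⁻⁶) are merged into one entry whose multiplicity
counts the members, and systematic absences (|F|² < 10⁻⁸ of the
maximum) are dropped. Each surviving reflection contributes a unit-area
pseudo-Voigt peak — a Gaussian/Lorentzian mixture with shared FWHM —
scaled by multiplicity × |F|² × LP, and the summed profile is
normalized to a maximum of 100.

Defaults mirror a routine laboratory acquisition of such samples:
Cu Kα₁ (λ = 1.5406 Å; an optional flag adds the Kα₂ doublet at
1.5444 Å with half weight), scan 20°–60° 2θ on a 0.02° grid, FWHM
0.15° 2θ, mixing fraction η = 0.5. The hkl enumeration bound
|h|,|k|,|l| ≤ ⌈max cell edge / d_min⌉ with d_min = λ/(2 sin θ_max)
covers the full sphere without per-space-group multiplicity tables.
Preferred orientation, absorption and instrument aberrations are
deliberately not modeled: the comparison is positional and
relative-intensity matching, and both sides of the comparison are
normalized.

Note on the LP convention: the unpolarized-beam form above has its
minimum near 2θ ≈ 98°; conventions that include a monochromator
polarization term place it elsewhere. The form used here is declared,
and the tests locate the minimum numerically rather than assuming a
textbook figure.

## The matching score

The experimental diffractogram is preprocessed (optional polynomial
background fitted to rolling minima and subtracted, negatives clipped,
normalized to max 100, resampled to the evaluation grid), then both the
experimental and each simulated spectrum are approximated by a smooth
model of normalized intensity versus 2θ. Candidate *i* receives

score_i = MAE_i / p_i

where MAE_i is the mean absolute error between the two spectral models
over the 2001-point grid and p_i is a Boltzmann probability over the
per-atom formation energies of the scored candidates,
p_i ∝ exp(−E_i/kT_eff). The lowest score wins; at equal misfit the more
stable phase is preferred. Dividing by p_i is the only reading of
"misfit per formation probability" that rewards low formation energy,
and it leaves the decision scale-invariant in the experimental
intensities.

Two knobs deserve comment:

* **T_eff (default 10⁴ K).** The formation energies are consumed as
  eV/atom (the convention of the source catalog). The ten most stable
  CaCO₃ polymorphs span only ~0.3 eV/atom, so a physical 300 K would
  collapse essentially all probability onto the single most stable
  phase and the spectra would never matter. At kT_eff ≈ 0.86 eV the
  weighting is strong but not degenerate — the four fixture candidates
  receive probabilities between 0.20 and 0.29 — and T_eff is exposed in
  `match_config()` so the sensitivity of a ranking can be audited.
* **Model kind.** The default spectral model is a cubic smoothing
  spline (`stats::smooth.spline`, all knots): deterministic,
  fast, and faithful to sharp peaks. A single-hidden-layer feed-forward
  regressor (`nnet`, logistic hidden units, linear output, full-batch
  training from a seeded initialization; defaults width 32, 2000
  iterations, seed 42) is available as `model_kind = "network"`. The
  network underfits narrow peaks — by design it is a smoother — but the
  two model kinds agree on the identified phase in every recovery test,
  which is the property that matters. Determinism is prioritized
  throughout: identical inputs and seeds give bit-identical rankings.

Candidates without atomic structures cannot be simulated; they are
skipped with a warning and excluded from the probability normalization
rather than penalized, since an unscorable candidate is not evidence
either way.

## The candidate catalog and fixtures

`load_candidate_catalog()` returns the 14 CaCO₃ polymorph entries
(materials id, space group, formation energy, band gap, cell volume,
atom count, density) packaged with the artifact. Every entry is
validated on construction: the atom count must be a whole number of
CaCO₃ units and the stored density must agree with the density
recomputed from volume, atom count and the molar mass (Ca 40.078,
C 12.011, O 15.999 g/mol; N_A = 6.02214076 × 10²³) to within
0.002 g/cc.

`make_reference_structures()` generates the four structures the test
suite matches against:

* **Calcite (mp-3953):** the standard conventional hexagonal R-3c cell
  (a = 4.9896 Å, c = 17.061 Å; Ca at 6b, C at 6a, O at 18e with
  x = 0.2567), expanding to 30 atoms — three primitive 10-atom cells,
  since the R-centred setting triples the primitive rhombohedral cell
  the catalog entry describes. Its simulated pattern has the textbook
  calcite signature (strongest peak (104) at 29.40°).
* **Vaterite (mp-560265):** a *synthetic* P6₅22 model. The source
  catalog gives the cell volume (1174.591 ų) and atom count (90) but
  no coordinates, so the fixture places two Ca, two C and five O
  orbits (12-fold general positions plus 6-fold special positions on
  the twofold axes) in a cell chosen to reproduce the catalog volume
  and density exactly. It is a stand-in with the right symmetry,
  stoichiometry and density, not a refined structure; its pattern is a
  stable, distinctive fixture, nothing more.
* **Two decoys** (mp-3205- and mp-548403-like): 10-atom orthorhombic
  toy cells listed explicitly in P1 at the catalog volumes, so the
  ranking always has energetically plausible wrong answers available.

`add_measurement_noise()` adds seeded Gaussian noise (scaled to the
maximum intensity) and an optional polynomial background, then clips at
zero. This emulates counting noise and background drift; it does not
emulate peak shifts from specimen displacement, texture, or amorphous
humps from organic residue. Passing the recovery tests therefore shows
robustness to statistical noise at the stated level, not to every
artifact of real biogenic samples — the preprocessing's background
subtraction and the normalization give some protection against the
latter, but no claim is tested.

`random_elastic_constants()` rejection-samples hexagonal/trigonal
tensors from uniform ranges (C₁₁, C₃₃ ∈ [50, 400]; C₁₂, C₁₃, C₄₄ ∈
[10, 150]; trigonal C₁₄ ∈ [−30, 30] GPa) until the Born criteria hold
(C₄₄ > 0, C₁₁ > |C₁₂|, (C₁₁ + C₁₂)C₃₃ > 2C₁₃²) — wide enough to cover
carbonates and far stiffer materials.

## Voigt–Reuss–Hill averaging

`vrh()` converts a Born-stable tensor into the four-row table of
polycrystalline bulk, Young's and shear moduli and Poisson's ratio
(Voigt, Reuss, Hill, and the per-column mean of the three as
"Average"), with the ductility class taken from the Hill ν at the
threshold 0.26 (ν ≥ 0.26 is ductile, boundary inclusive).

Two design points:

* **Formula variant.** Some published statements of the hexagonal
  Voigt/Reuss bulk formulas contain typographic losses
  ("+ C₃₃ + C₁₃" where the standard form has "+ 4C₁₃ + C₃₃", and a
  Reuss denominator "C₁₁ + C₁₂ + C₃₃ − C₁₃" where the standard form has
  "2C₃₃ − 4C₁₃"). The shear formulas in the same sources expand
  *exactly* to the standard expressions, which identifies the bulk
  variants as typos rather than a different convention. The default is
  the standard forms; `variant = "as_printed"` reproduces the literal
  text so the discrepancy stays auditable.
* **Trigonal handling.** The averaging expressions involve only C₁₁,
  C₁₂, C₁₃, C₃₃, C₄₄, C₆₆. Trigonal tensors are averaged with the same
  hexagonal-form expressions; C₁₄ (and C₁₅) are stored and reported but
  do not enter. A strict full-trigonal Reuss average is out of scope.

When only the polycrystalline Voigt/Reuss bounds are known — the common
situation when reproducing published tables whose single-crystal
constants are not printed — `vrh_from_bounds()` builds the same table
from (B_V, G_V, B_R, G_R). Reported tables round half-to-even to three
decimals; full precision is kept on the object.

## Numerical choices and degenerate inputs

* Duplicate-site merge tolerance after symmetry expansion: 10⁻³ in
  fractional coordinates on all three axes (with wrap-around) —
  standard crystallographic practice, far below any physical
  distinction.
* CIF dialect: one data block, core cell/symmetry/atom-site tags only;
  a file without an operator loop is treated as P1. The writer emits
  the same dialect, so structures round-trip.
* Reflections with λ > 2d simply do not diffract: they are excluded,
  not raised as errors; an empty scan window yields an all-zero pattern
  with a warning.
* All-zero patterns cannot be normalized (error); spectra that do not
  cover the evaluation grid are a coverage error; fewer than 10 grid
  points is an insufficient-data error.
* Ranking ties break toward the lower formation energy; degenerate
  elastic denominators and Born violations raise errors naming the
  violated criterion.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make the
statistical checks meaningful while keeping a full run around half a
minute: 20 seeded noisy spectra per fixture phase at 2 % noise for the
recovery experiment (with ≥ 19/20 required per phase), 1000 random
tensors for the Voigt ≥ Reuss bound ordering, and 100 random cases each
for the structure-factor and d-spacing oracle comparisons (brute-force
complex sums and explicit reciprocal bases, agreement to relative
10⁻⁸). Simulated candidate patterns are cached per session, keyed by
candidate id and validated against the exact structure and settings, so
repeated identifications do not redo identical simulations.

## Limitations

* The sample is assumed single-phase: there is no mixture or
  phase-fraction decomposition, and a diffractogram of a true mixture
  will be forced onto whichever single candidate fits best.
* Matching quality is bounded by the candidate set: a phase missing
  from the catalog (or present without coordinates) cannot be found.
* The simulator is not a Rietveld engine — no refinement of cell,
  profile or texture against the data.
* Single-crystal elastic constants are inputs; computing them from
  first principles is outside the package. Published polycrystalline
  tables can be reproduced exactly only from their printed bounds when
  the underlying constants are unpublished.
* The vaterite fixture is synthetic (see above); conclusions about real
  vaterite intensities should use a refined structure supplied as a
  CIF.
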