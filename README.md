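# calcphase

Phase identification and polycrystalline elastic moduli of biogenic
calcium carbonate from powder X-ray diffraction.

Microbially induced calcium carbonate precipitation (MICP) produces
CaCO₃ whose polymorph — trigonal calcite, hexagonal vaterite,
orthorhombic aragonite, or a rarer metastable form — controls how useful
the mineral is as a biocement additive. `calcphase` answers two
questions about such a precipitate:

1. **Which crystal phase is it?** Candidate structures are turned into
   simulated powder diffractograms (Cu Kα, 20°–60° 2θ), both the
   experimental and simulated spectra are normalized and approximated by
   smooth spectral models, and every candidate *i* is scored by

   score_i = MAE_i / p_i,   p_i = exp(−E_i / k T_eff) / Σ_j exp(−E_j / k T_eff)

   where MAE_i is the mean absolute error between the spectral models on
   the evaluation grid, E_i is the candidate's formation energy per atom
   (eV), and p_i its Boltzmann formation probability. The lowest score
   identifies the phase: a candidate must both fit the spectrum and be
   energetically plausible.

2. **How stiff is it?** Single-crystal elastic constants C₁₁, C₁₂, C₁₃,
   C₃₃, C₄₄ (with C₆₆ = (C₁₁ − C₁₂)/2) of the identified
   hexagonal/trigonal phase are converted to polycrystalline moduli by
   Voigt–Reuss–Hill averaging:

   - B_V = [2(C₁₁ + C₁₂) + 4C₁₃ + C₃₃]/9,
     G_V = [7C₁₁ − 5C₁₂ + 12C₄₄ + 2C₃₃ − 4C₁₃]/30
   - B_R = C²/(C₁₁ + C₁₂ + 2C₃₃ − 4C₁₃),
     G_R = 5C²C₄₄C₆₆ / [6B_V C₄₄C₆₆ + 2C²(C₄₄ + C₆₆)],
     with C² = (C₁₁ + C₁₂)C₃₃ − 2C₁₃²
   - B_H = (B_V + B_R)/2, G_H = (G_V + G_R)/2
   - E = 9BG/(3B + G), ν = (3B − 2G)/(2(3B + G))

   A Poisson's ratio below 0.26 classifies the aggregate as brittle,
   otherwise ductile.

The package also ships the supporting pieces: a 14-entry candidate
catalog of CaCO₃ polymorphs (id, space group, formation energy, cell
volume, atom count, density), a scoped CIF reader/writer, synthetic
fixture generators (reference structures, seeded noisy spectra, random
Born-stable elastic tensors), and the assay arithmetic used in biocement
studies (precipitate weight by filter difference, compressive-strength
gain).

## Worked example

Identify the phase of a noisy vaterite-like spectrum against the
fixture candidates, then report the elastic moduli of biogenic calcite
from its polycrystalline Voigt/Reuss bounds:

```r
library(calcphase)

structs <- make_reference_structures()
cands   <- fixture_candidates()          # catalog + fixture structures

clean <- simulate_pattern(structs[["mp-560265"]])
noisy <- add_measurement_noise(clean, sigma_frac = 0.02, seed = 42)
identify_phase(noisy, cands)
#> <phase_match> identified mp-560265 (P6_522): MAE 0.7311, p 0.282, score 2.589
#>   4 candidate(s) scored; model kind 'spline'

vrh_from_bounds(b_v = 81.32, g_v = 37.188, b_r = 74.309, g_r = 30.103)
#> Voigt-Reuss-Hill polycrystalline moduli:
#>  Averaging scheme Bulk modulus (GPa) Young's modulus (GPa) Shear modulus (GPa) Poisson's ratio
#>             Voigt             81.320                96.807              37.188           0.302
#>             Reuss             74.309                79.565              30.103           0.322
#>              Hill             77.814                88.221              33.645           0.311
#>           Average             77.814                88.198              33.645           0.311
#> Ductility (Hill nu >= 0.26): ductile
```

The identification line says the hexagonal P6₅22 vaterite model is the
best-scoring candidate (smallest MAE per formation probability); the
elasticity table gives the uniform-strain (Voigt) upper bound, the
uniform-stress (Reuss) lower bound, their Hill means, and the derived
Young's modulus and Poisson's ratio — a Hill ν of 0.311 classifies the
aggregate as ductile.

The same operations are available from a shell:

```sh
Rscript inst/cli/calcphase fixtures --out fixtures/ --seed 42
Rscript inst/cli/calcphase identify --experimental fixtures/mp-560265_noisy.xy \
        --structures fixtures/
Rscript inst/cli/calcphase elastic --constants bounds.json
Rscript inst/cli/calcphase assay --treatment 37.02 --control 29.05
```

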