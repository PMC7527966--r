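test_that("formation probabilities follow the Boltzmann law", {
  mk <- function(e, id) candidate_phase(id, "P1", e, NA, 127.17, 10, 2.614)
  # equal energies: uniform
  p <- formation_probability(list(mk(-2.7, "a"), mk(-2.7, "b"),
                                  mk(-2.7, "c")))
  expect_equal(as.numeric(p), rep(1 / 3, 3))
  # two candidates split by kT ln 2: probabilities 2/3 and 1/3
  kT <- 8.617333262e-5 * 1e4
  p2 <- formation_probability(list(mk(-2.7, "low"),
                                   mk(-2.7 + kT * log(2), "high")))
  expect_equal(as.numeric(p2), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # full catalog: the lowest-energy phase gets the largest probability
  pc <- formation_probability(load_candidate_catalog())
  expect_identical(names(which.max(pc)), "mp-3953")
  expect_equal(sum(pc), 1, tolerance = 1e-12)
  # strictly decreasing in formation energy
  cat14 <- load_candidate_catalog()
  e <- vapply(cat14, function(x) x$formation_energy, numeric(1))
  expect_true(all(diff(pc[order(e)]) <= 0))
  expect_error(formation_probability(list()), "non-empty")
})

test_that("experimental preprocessing normalizes, resamples and removes background", {
  cfg <- match_config()
  pat <- simulate_pattern(ref_structs[["mp-3953"]])
  # identity path: already normalized, matching grid, background off
  out <- preprocess_experimental(pat, cfg)
  expect_equal(out$intensity, pat$intensity, tolerance = 1e-12)
  # constant offset removed with degree-0 background
  off <- powder_pattern(pat$two_theta, pat$intensity + 30)
  cfg0 <- match_config(background_degree = 0)
  out0 <- preprocess_experimental(off, cfg0)
  expect_equal(out0$intensity, out$intensity, tolerance = 0.05)
  # noisy pattern: output max is exactly 100
  noisy <- add_measurement_noise(pat, sigma_frac = 0.02, seed = 5)
  expect_equal(max(preprocess_experimental(noisy, cfg)$intensity), 100)
  # grid not covered
  short <- powder_pattern(seq(25, 60, 0.02),
                          rep(1, length(seq(25, 60, 0.02))))
  expect_error(preprocess_experimental(short, cfg), "cover")
})

test_that("spectrum models fit their training spectra and are deterministic", {
  pat <- simulate_pattern(ref_structs[["mp-3953"]])
  m <- fit_spectrum_model(pat, match_config())
  expect_lte(m$training_mae, 0.5)
  # deterministic: identical inputs give identical fits
  m2 <- fit_spectrum_model(pat, match_config())
  expect_identical(predict(m, pat$two_theta), predict(m2, pat$two_theta))
  # network path: same seed, same weights
  cfgn <- match_config(model_kind = "network", network_width = 8,
                       network_epochs = 100, seed = 7)
  n1 <- fit_spectrum_model(pat, cfgn)
  n2 <- fit_spectrum_model(pat, cfgn)
  expect_identical(n1$fit$wts, n2$fit$wts)
  # constant spectrum: predicted constant everywhere
  cpat <- powder_pattern(seq(20, 60, 0.02), rep(100, 2001),
                         normalized = TRUE)
  mc <- fit_spectrum_model(cpat, cfgn)
  expect_lt(max(abs(predict(mc, seq(20, 60, 1)) - 100)), 0.1)
  # too few points
  expect_error(fit_spectrum_model(powder_pattern(1:5, rep(1, 5)),
                                  match_config()),
               "insufficient")
})

test_that("MAE between spectra equals the brute-force definition", {
  grid <- seq(20, 60, 0.02)
  pa <- powder_pattern(grid, abs(sin(grid)) * 100)
  pb <- powder_pattern(grid, abs(cos(grid)) * 100)
  expect_equal(mae_between(pa, pa, grid), 0)
  pshift <- powder_pattern(grid, abs(sin(grid)) * 100 + 5)
  expect_equal(mae_between(pa, pshift, grid), 5, tolerance = 1e-12)
  brute <- 0
  for (i in seq_along(grid))
    brute <- brute + abs(abs(sin(grid[i])) - abs(cos(grid[i]))) * 100
  expect_equal(mae_between(pa, pb, grid), brute / length(grid),
               tolerance = 1e-12)
  expect_error(mae_between(pa, pb, numeric()), "non-empty")
})

test_that("exact simulated patterns self-match with ~zero error", {
  for (id in c("mp-3953", "mp-560265")) {
    pat <- simulate_pattern(ref_structs[[id]])
    res <- suppressWarnings(identify_phase(pat, fix_cands))
    expect_identical(res$best$materials_id, id)
    expect_lt(res$best$mae, 1e-6)
  }
})

test_that("ranking is scale invariant and conserves probability", {
  pat <- simulate_pattern(ref_structs[["mp-560265"]])
  noisy <- add_measurement_noise(pat, sigma_frac = 0.02, seed = 9)
  r1 <- suppressWarnings(rank_candidates(noisy, fix_cands))
  scaled <- powder_pattern(noisy$two_theta, noisy$intensity * 3.7)
  r2 <- suppressWarnings(rank_candidates(scaled, fix_cands))
  expect_equal(r1$ranking$score, r2$ranking$score, tolerance = 1e-9)
  expect_identical(r1$ranking$materials_id, r2$ranking$materials_id)
  # probabilities over the scored set sum to 1; score = mae / probability
  expect_equal(sum(r1$ranking$probability), 1, tolerance = 1e-9)
  expect_equal(r1$ranking$score,
               r1$ranking$mae / r1$ranking$probability)
  expect_true(all(diff(r1$ranking$score) >= 0))
  # structureless candidates are skipped with a warning
  expect_warning(rank_candidates(noisy, fix_cands), "skipping")
  # no usable candidates at all
  expect_error(rank_candidates(noisy, load_candidate_catalog()),
               "no usable")
})

test_that("at equal spectral error the more stable phase wins", {
  # two entries sharing one structure: identical MAE, ranking then
  # follows formation probability (lower energy first)
  st <- ref_structs[["mp-3205"]]
  a <- candidate_phase("toy-lo", "Pmmn", -2.6, NA, 110.731, 10, 3.002,
                       structure = st)
  b <- candidate_phase("toy-hi", "Pmmn", -2.4, NA, 110.731, 10, 3.002,
                       structure = st)
  pat <- simulate_pattern(st)
  res <- rank_candidates(pat, list(b, a))
  expect_equal(res$ranking$mae[1], res$ranking$mae[2], tolerance = 1e-12)
  expect_identical(res$ranking$materials_id[1], "toy-lo")
})

test_that("noisy spectra are recovered for every fixture phase", {
  ids <- names(ref_structs)
  for (id in ids) {
    clean <- simulate_pattern(ref_structs[[id]])
    for (seed in 1:3) {
      noisy <- add_measurement_noise(clean, sigma_frac = 0.02, seed = seed)
      res <- suppressWarnings(identify_phase(noisy, fix_cands))
      expect_identical(res$best$materials_id, id)
    }
  }
})

test_that("spline and network models agree on the identified phase", {
  cfgn <- match_config(model_kind = "network", network_width = 16,
                       network_epochs = 400)
  for (id in names(ref_structs)) {
    clean <- simulate_pattern(ref_structs[[id]])
    noisy <- add_measurement_noise(clean, sigma_frac = 0.02, seed = 11)
    rs <- suppressWarnings(identify_phase(noisy, fix_cands))
    rn <- suppressWarnings(identify_phase(noisy, fix_cands, cfgn))
    expect_identical(rs$best$materials_id, id)
    expect_identical(rn$best$materials_id, id)
  }
})
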