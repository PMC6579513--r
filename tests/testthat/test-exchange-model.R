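test_that("protein model enforces its physical invariants", {
  expect_error(tiny_protein(log10P = c(-0.1, rep(0, 11))), "P >= 1")
  expect_error(tiny_protein(k_int = c(0, rep(0.1, 11))), "rates")
  expect_error(
    hdx_protein("GAST", regions = data.frame(name = "X", start = 1,
                                             end = 9),
                log10_protection = rep(0, 4), k_int = rep(1, 4)),
    "within")
  p <- synthetic_protein(seed = 7)
  expect_true(all(p$log10_protection >= 0))
  expect_true(all(p$k_int > 0))
  expect_true(grepl("P", p$sequence))
  # same seed, same construct
  expect_identical(p, synthetic_protein(seed = 7))
  # fast C-terminal intrinsic window
  fast <- unlist(lapply(c("H10", "H11", "H12"), region_residues,
                        protein = p)) - p$first_index + 1L
  expect_true(min(log10(p$k_int[fast])) >= -1.3 - 1e-9)
})

test_that("residue exchange follows the closed-form kinetics", {
  p <- tiny_protein(log10P = rep(0, 12), k_int = rep(0.1, 12))
  expect_equal(residue_fraction(p, NULL, 3, 10), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(residue_fraction(p, NULL, 5, 0), 0)
  p2 <- tiny_protein(log10P = rep(12, 12))
  expect_lt(residue_fraction(p2, NULL, 3, 14400), 1e-6)
  expect_error(residue_fraction(p, NULL, 3, -1), "time")
  expect_error(residue_fraction(p, NULL, 13, 10), "outside")
})

test_that("uptake is monotone in time and antitone in protection", {
  p <- synthetic_protein(seed = 3)
  res <- p$first_index:(p$first_index + 30L)
  ts <- c(0, 10, 30, 110, 380, 1270, 4270, 14400)
  fr <- vapply(ts, function(t) residue_fraction(p, NULL, res, t),
               numeric(length(res)))
  expect_true(all(diff(t(fr)) >= 0))
  cmp_weak <- compound_spec("w", "partial_agonist", c(H1 = 0.5))
  cmp_strong <- compound_spec("s", "partial_agonist", c(H1 = 2.0))
  h1 <- region_residues(p, "H1")
  for (t in c(10, 1270, 14400)) {
    f0 <- residue_fraction(p, NULL, h1, t)
    fw <- residue_fraction(p, cmp_weak, h1, t)
    fs <- residue_fraction(p, cmp_strong, h1, t)
    expect_true(all(fw <= f0 + 1e-12))
    expect_true(all(fs <= fw + 1e-12))
  }
  # occupancy scales the planted effect
  half <- compound_spec("h", "partial_agonist", c(H1 = 2.0),
                        occupancy = 0.5)
  expect_true(all(residue_fraction(p, half, h1, 110) >=
                  residue_fraction(p, cmp_strong, h1, 110) - 1e-12))
})

test_that("peptide observations match the analytic mean at zero noise", {
  p <- tiny_protein(log10P = seq(0, 2.2, length.out = 12),
                    k_int = rep(0.05, 12))
  pep <- tiny_peptides()[1, ]
  cfg <- sim_config(timepoints = c(10, 110, 14400), n_replicates = 2,
                    noise_sd = 0, seed = 11)
  obs <- simulate_peptide_observations(p, pep, NULL, cfg)
  ex <- exchangeable_residues(pep$start, pep$end, pep$sequence)
  for (t in c(10, 110, 14400)) {
    truth <- 100 * mean(residue_fraction(p, NULL, ex, t))
    got <- obs$percent_d[obs$timepoint_s == t]
    expect_equal(got, rep(truth, 2), tolerance = 1e-9)
  }
})

test_that("observations are deterministic given the seed and bounded", {
  p <- synthetic_protein(seed = 5)
  pep <- generate_peptide_map(p, seed = 5)
  cmp <- simulate_compound_library(4, seed = 5)
  cfg <- sim_config(timepoints = c(10, 14400), n_replicates = 3,
                    noise_sd = 8, seed = 9)
  a <- simulate_hdx_dataset(p, pep, cmp, cfg)
  b <- simulate_hdx_dataset(p, pep, cmp, cfg)
  expect_identical(a, b)
  expect_true(all(a$percent_d >= 0 & a$percent_d <= 100))
})

test_that("raw centroid mode round-trips through percent_deuterium", {
  p <- tiny_protein()
  pep <- tiny_peptides()[2, ]
  cfg <- sim_config(timepoints = c(10, 380), n_replicates = 2,
                    noise_sd = 0, seed = 2)
  raw <- simulate_peptide_observations(p, pep, NULL, cfg, raw = TRUE)
  plain <- simulate_peptide_observations(p, pep, NULL, cfg, raw = FALSE)
  back <- percent_deuterium(raw$undeut_mz, raw$obs_mz, raw$dmax_mz)
  expect_equal(back, plain$percent_d, tolerance = 1e-9)
})

test_that("peptide map generation hits coverage and count presets", {
  p <- synthetic_protein(seed = 21)
  # default preset: 54 peptides, ~98% coverage of 254 residues
  pep <- generate_peptide_map(p, seed = 21)
  expect_equal(nrow(pep), 54L)
  cov <- sequence_coverage(pep, 254, p$first_index)
  expect_gte(cov, 96); expect_lte(cov, 100)
  expect_identical(pep, generate_peptide_map(p, seed = 21))
  # full tiling of a toy sequence
  toy <- hdx_protein(paste(rep("A", 20), collapse = ""), 1,
                     data.frame(name = "X", start = 1, end = 20),
                     rep(0, 20), rep(1, 20))
  tiled <- generate_peptide_map(toy, n_peptides = 4,
                                target_coverage = 1, mean_length = 6,
                                seed = 1)
  expect_equal(sequence_coverage(tiled, 20, 1), 100)
  # infeasible demand
  expect_error(generate_peptide_map(p, n_peptides = 5,
                                    target_coverage = 0.98,
                                    max_length = 10),
               "unreachable")
})

test_that("compound library respects class proportions and signatures", {
  lib <- simulate_compound_library(5, c(agonist = 1), seed = 1)
  expect_length(lib, 5)
  expect_true(all(vapply(lib, function(x)
    x$region_effects[["H12"]] > 0, logical(1))))
  nulls <- simulate_compound_library(4, c(null = 1), seed = 1)
  expect_true(all(vapply(nulls, function(x)
    length(x$region_effects) == 0L, logical(1))))
  expect_error(simulate_compound_library(4, c(superagonist = 1)),
               "unknown class")
  mixed <- simulate_compound_library(38, seed = 2)
  expect_equal(as.integer(table(attr(mixed, "classes"))[
    c("agonist", "inverse_agonist", "partial_agonist")]),
    c(13L, 13L, 12L))
})

test_that("assay activities are linear in the planted score", {
  p <- synthetic_protein(seed = 4)
  lib <- simulate_compound_library(10, seed = 4)
  link <- assay_link_model(
    alphascreen = list(regions = "H12", timepoint = 10,
                       intercept = 100, slope = -50, noise_sd = 0))
  act <- simulate_activities(p, lib, link, seed = 1)
  a <- act[act$assay == "alphascreen", ]
  sc <- regional_score(p, lib, "H12", 10)
  expect_equal(a$value, 100 - 50 * unname(sc), tolerance = 1e-9)
  expect_equal(stats::cor(a$value, sc)^2, 1, tolerance = 1e-9)
  # an assay linked to a region the protein lacks is an error
  bad <- assay_link_model(
    alphascreen = list(regions = "H99", timepoint = 10,
                       intercept = 0, slope = 1, noise_sd = 0))
  expect_error(simulate_activities(p, lib, bad, seed = 1),
               "unknown region")
})
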