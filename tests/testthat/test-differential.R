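test_that("perturbation delta and Welch test behave at the contracts", {
  # constant arms: delta is exact, zero-variance flag governs p
  r <- delta_percent_d(c(40, 40, 40), c(55, 55, 55))
  expect_equal(r$delta, -15)
  expect_equal(r$p_value, 0)
  expect_equal(r$flag, "zero-variance")
  r2 <- delta_percent_d(c(50, 51, 49), c(50, 51, 49))
  expect_equal(r2$delta, 0)
  expect_equal(r2$p_value, 1)
  expect_error(delta_percent_d(50, c(50, 50)), ">= 2 replicates")
  expect_equal(delta_percent_d(50, c(40, 60), p_value = FALSE)$delta, 0)
  # Welch p against an independent computation from first principles
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(sample(3:6, 1), 50, 2); b <- rnorm(sample(3:6, 1), 48, 3)
    got <- delta_percent_d(a, b)
    se2 <- var(a) / length(a) + var(b) / length(b)
    tval <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
    expect_equal(got$t_statistic, tval, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * pt(-abs(tval), df), tolerance = 1e-9)
    # antisymmetry
    swapped <- delta_percent_d(b, a)
    expect_equal(swapped$delta, -got$delta, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  with_na <- bh_adjust(c(NA, 0.5, 0.01))
  expect_true(is.na(with_na[1]))
  expect_equal(with_na[2:3], brute_bh(c(0.5, 0.01)))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    got <- bh_adjust(p)
    expect_equal(got, brute_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
  }
})

test_that("perturbation matrix pairs every compound cell with vehicle", {
  p <- synthetic_protein(seed = 31)
  pep <- generate_peptide_map(p, n_peptides = 12, seed = 31)
  lib <- simulate_compound_library(4, seed = 31)
  cfg <- sim_config(timepoints = c(10, 14400), n_replicates = 4,
                    noise_sd = 1.5, seed = 31)
  obs <- simulate_hdx_dataset(p, pep, lib, cfg)
  pm <- perturbation_matrix(obs)
  expect_equal(dim(pm$delta), c(4L, 24L))
  expect_equal(sort(rownames(pm$delta)),
               sort(vapply(lib, `[[`, "", "id")))
  # deltas agree with direct group-mean differences
  one <- pm$records[1, ]
  tr <- obs$percent_d[obs$condition == one$compound &
                      obs$peptide_id == one$peptide_id &
                      obs$timepoint_s == one$timepoint_s]
  ve <- obs$percent_d[obs$condition == "vehicle" &
                      obs$peptide_id == one$peptide_id &
                      obs$timepoint_s == one$timepoint_s]
  expect_equal(one$delta, mean(tr) - mean(ve), tolerance = 1e-12)
  expect_true(all(pm$records$adjusted_p >= pm$records$p_value,
                  na.rm = TRUE))
  expect_error(perturbation_matrix(obs, vehicle = "dmso"), "absent")
  # a condition missing one cell yields NA, never zero
  obs2 <- obs[!(obs$condition == lib[[1]]$id &
                obs$peptide_id == pep$id[1] & obs$timepoint_s == 10), ]
  pm2 <- perturbation_matrix(obs2)
  expect_true(is.na(pm2$delta[lib[[1]]$id,
                              pm2$cells$label[pm2$cells$peptide_id ==
                                              pep$id[1] &
                                              pm2$cells$timepoint_s ==
                                              10]]))
})

test_that("screening filter applies the N-compound rule at the boundary", {
  # hand-built records: one cell with exactly 15 significant compounds,
  # one with 14, one with none
  n_cmp <- 38L
  cells <- c("A", "B", "C")
  rec <- expand.grid(compound = sprintf("C%02d", 1:n_cmp), label = cells,
                     stringsAsFactors = FALSE)
  rec$peptide_id <- rec$label; rec$timepoint_s <- 10
  rec$delta <- -6; rec$t_statistic <- -5
  rec$p_value <- 0.5; rec$adjusted_p <- 0.5
  sig_a <- rec$label == "A" & rec$compound %in% sprintf("C%02d", 1:15)
  sig_b <- rec$label == "B" & rec$compound %in% sprintf("C%02d", 1:14)
  rec$adjusted_p[sig_a | sig_b] <- 0.01
  rec$significant <- rec$adjusted_p < 0.05
  rec$flag <- ""
  pm <- structure(list(
    records = rec,
    delta = matrix(-6, n_cmp, 3,
                   dimnames = list(sprintf("C%02d", 1:n_cmp), cells)),
    cells = data.frame(peptide_id = cells, timepoint_s = 10,
                       label = cells),
    compounds = sprintf("C%02d", 1:n_cmp), vehicle = "vehicle",
    config = significance_config()), class = "hdx_perturbation")
  f <- significance_filter(pm)
  expect_equal(f$kept$label, "A")
  expect_equal(f$counts, c(15L, 14L, 0L))
  # fractional rule reproduces the absolute rule at 15/38
  f2 <- significance_filter(pm, significance_config(
    min_significant_compounds = NULL,
    min_significant_fraction = 15 / 38))
  expect_equal(f2$kept$label, "A")
  # magnitude threshold can veto small deltas
  pm$records$delta <- -2
  f3 <- significance_filter(pm, significance_config(
    magnitude_threshold = 5))
  expect_equal(nrow(f3$kept), 0L)
})

test_that("mean perturbation averages available timepoints only", {
  rec <- data.frame(compound = "C01", peptide_id = "p1",
                    timepoint_s = c(10, 14400, 380),
                    label = paste0("p1-", c(10, 14400, 380)),
                    delta = c(-10, -20, NA), t_statistic = NA,
                    p_value = NA, adjusted_p = NA, flag = "",
                    significant = FALSE)
  pm <- structure(list(records = rec), class = "hdx_perturbation")
  mp <- mean_perturbation(pm)
  expect_equal(mp$mean_delta, -15)
  expect_equal(mp$n_timepoints, 2L)
})
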