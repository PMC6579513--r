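test_that("activity correlation recovers exact linear couplings", {
  set.seed(5)
  x <- rnorm(10, -20, 8)
  delta <- cbind(cellA = x, cellB = rep(-3, 10),
                 cellC = rnorm(10))
  rownames(delta) <- sprintf("C%02d", 1:10)
  pm <- fake_perturbation(delta)
  act <- data.frame(compound = rownames(delta), assay = "alphascreen",
                    value = 2 * x + 1)
  # a noiseless coupling triggers lm's perfect-fit warning; harmless here
  cc <- suppressWarnings(activity_correlation(pm, act, "alphascreen"))
  a <- cc[cc$label == "cellA", ]
  expect_equal(a$r_squared, 1, tolerance = 1e-9)
  expect_equal(a$slope, 2, tolerance = 1e-9)
  expect_equal(a$intercept, 1, tolerance = 1e-6)
  expect_true(a$significant && a$predictive)
  # constant perturbation is flagged out of the family
  expect_equal(cc$flag[cc$label == "cellB"], "constant-perturbation")
  expect_true(is.na(cc$adjusted_p[cc$label == "cellB"]))
  # r^2 is invariant to affine rescaling of the activity
  act2 <- transform(act, value = -0.3 * value + 100)
  cc2 <- suppressWarnings(activity_correlation(pm, act2, "alphascreen"))
  expect_equal(cc2$r_squared[cc2$label == "cellC"],
               cc$r_squared[cc$label == "cellC"], tolerance = 1e-9)
  expect_error(activity_correlation(pm, act, "thermal_shift"),
               "no activity")
})

test_that("covariation grid is symmetric with unit diagonal", {
  set.seed(8)
  x <- rnorm(12)
  delta <- cbind(a = x, b = -2 * x + rnorm(12, 0, 1e-8),
                 c = rnorm(12), d = rnorm(12))
  rownames(delta) <- sprintf("C%02d", 1:12)
  cv <- covariation(fake_perturbation(delta))
  expect_equal(diag(cv$r2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cv$r2, t(cv$r2))
  expect_equal(cv$mask, t(cv$mask))
  # anticorrelation gives r^2 of 1: the sign is lost in r-squared
  expect_equal(cv$r2["a", "b"], 1, tolerance = 1e-9)
  expect_lt(cv$records$r[cv$records$x == "a" & cv$records$y == "b"], 0)
  # independent noise columns are rarely unmasked at adjusted p < 0.01
  set.seed(9)
  hits <- vapply(1:30, function(i) {
    d <- cbind(u = rnorm(38), v = rnorm(38), w = rnorm(38))
    rownames(d) <- sprintf("C%02d", 1:38)
    m <- covariation(fake_perturbation(d))$mask
    any(m[upper.tri(m)])
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("Ward clustering merges identical signatures at height zero", {
  delta <- rbind(C1 = c(1, 2, 3), C2 = c(1, 2, 3), C3 = c(9, 9, 9))
  colnames(delta) <- c("x", "y", "z")
  cl <- cluster_compounds(fake_perturbation(delta))
  expect_equal(min(cl$height), 0)
  expect_equal(length(cl$height), 2L)  # n - 1 merges
  expect_true(all(diff(cl$height) >= 0))  # Ward heights nondecreasing
  expect_equal(unname(cut_clusters(cl, 2)[c("C1", "C2")]),
               c(1L, 1L))
  expect_error(cluster_compounds(fake_perturbation(delta[1, ,
                                                         drop = FALSE])),
               ">= 2")
})

test_that("clustering separates well-planted groups and ignores row order", {
  set.seed(11)
  g1 <- matrix(rnorm(5 * 6, 0, 1), 5, 6)
  g2 <- matrix(rnorm(4 * 6, -30, 1), 4, 6)
  delta <- rbind(g1, g2)
  rownames(delta) <- sprintf("C%02d", 1:9)
  colnames(delta) <- sprintf("cell%d", 1:6)
  cl <- cluster_compounds(fake_perturbation(delta))
  k2 <- cut_clusters(cl, 2)
  expect_equal(length(unique(k2[1:5])), 1L)
  expect_equal(length(unique(k2[6:9])), 1L)
  expect_false(k2[[1]] == k2[[9]])
  # permuting compound input order leaves the tree heights unchanged
  perm <- c(4, 9, 1, 7, 2, 5, 8, 3, 6)
  cl2 <- cluster_compounds(fake_perturbation(delta[perm, ]))
  expect_equal(sort(cl2$height), sort(cl$height), tolerance = 1e-9)
  # missing-cell policies
  delta_na <- delta; delta_na[1, 2] <- NA
  cl_drop <- cluster_compounds(fake_perturbation(delta_na))
  expect_equal(length(cl_drop$signature_cells), 5L)
  cl_imp <- cluster_compounds(fake_perturbation(delta_na),
                              na_action = "impute")
  expect_equal(length(cl_imp$signature_cells), 6L)
})

test_that("prediction-interval outlier flagging isolates displaced points", {
  set.seed(3)
  x <- seq(1, 20)
  y <- 3 * x + 2
  expect_length(flag_outliers(x, y, ids = paste0("C", 1:20)), 0L)
  y2 <- y + rnorm(20, 0, 0.5)
  y2[7] <- y2[7] + 10 * 0.5 * 10  # ten residual SDs away
  out <- flag_outliers(x, y2, ids = paste0("C", 1:20))
  expect_equal(unclass(out)[1], "C7", ignore_attr = TRUE)
  expect_error(flag_outliers(1:3, c(1, 2, 3), ids = letters[1:3]),
               ">= 4")
  expect_error(flag_outliers(rep(1, 5), rnorm(5), ids = letters[1:5]),
               "degenerate")
})
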