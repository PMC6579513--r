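test_that("single-peptide consolidation applies the exclusion rules", {
  pep <- hdx_peptides(data.frame(id = "p1", sequence = "ALSGQK",
                                 start = 10L, end = 15L, charge = 1L))
  m <- consolidate_to_residues(c(p1 = 20), pep, seq_length = 10,
                               first_index = 8L)
  # residues 12-15 covered (positions >= 3, no prolines here)
  expect_equal(m$value[m$residue %in% 12:15], rep(20, 4))
  expect_true(all(m$missing[m$residue %in% c(8, 9, 10, 11, 16, 17)]))
  expect_equal(m$depth[m$residue == 13], 1L)
  # prolines never receive a value
  pep2 <- hdx_peptides(data.frame(id = "p2", sequence = "ALSPQK",
                                  start = 10L, end = 15L, charge = 1L))
  m2 <- consolidate_to_residues(c(p2 = 20), pep2)
  expect_true(m2$missing[m2$residue == 13])
})

test_that("overlap consolidation is the inverse-length weighted mean", {
  # two peptides with 4 and 8 exchangeable residues share residue 20
  pep <- hdx_peptides(data.frame(
    id = c("s", "l"),
    sequence = c("AAGSTK", "AAGSTKLVNQ"),
    start = c(15L, 15L), end = c(20L, 24L), charge = 1L))
  expect_equal(exchangeable_residue_count(pep$sequence), c(4L, 8L))
  m <- consolidate_to_residues(c(s = 10, l = 30), pep)
  got <- m$value[m$residue == 20]
  expect_equal(got, (10 * 0.25 + 30 * 0.125) / 0.375, tolerance = 1e-9)
  expect_equal(got, 16.6667, tolerance = 1e-4)
  # the consolidated value sits strictly closer to the shorter peptide
  expect_lt(abs(got - 10), abs(got - 30))
  expect_equal(m$depth[m$residue == 20], 2L)
  # equal contributing values pass through unchanged
  m_eq <- consolidate_to_residues(c(s = 12, l = 12), pep)
  expect_equal(m_eq$value[!m_eq$missing],
               rep(12, sum(!m_eq$missing)))
})

test_that("consolidation matches a brute-force per-residue loop", {
  set.seed(13)
  for (i in 1:100) {
    pep <- random_peptide_table(sample(2:6, 1))
    if (is.null(pep)) next
    vals <- setNames(runif(nrow(pep), -30, 30), pep$id)
    m <- consolidate_to_residues(vals, pep, seq_length = 40,
                                 first_index = 1L)
    oracle <- brute_consolidate(vals, pep, 1L, 40L)
    expect_equal(m$value, oracle, tolerance = 1e-12)
    # convexity: within the range of contributing values
    covered <- !m$missing
    expect_true(all(m$value[covered] >= min(vals) - 1e-9))
    expect_true(all(m$value[covered] <= max(vals) + 1e-9))
  }
})

test_that("consolidation rejects degenerate inputs", {
  short <- hdx_peptides(data.frame(id = "x", sequence = "GL",
                                   start = 1L, end = 2L, charge = 1L))
  expect_error(consolidate_to_residues(c(x = 5), short),
               "no exchangeable")
  pep <- tiny_peptides()
  expect_error(consolidate_to_residues(c(bogus = 5), pep), "unknown")
  expect_error(consolidate_to_residues(c(p1 = 5), pep,
                                       weight_fun = function(n) -1),
               "positive")
})

test_that("sequence coverage is the union of full spans", {
  tile <- hdx_peptides(data.frame(
    id = c("a", "b"), sequence = c("AAAAA", "AAAAA"),
    start = c(1L, 6L), end = c(5L, 10L), charge = 1L))
  expect_equal(sequence_coverage(tile, 10), 100)
  one <- hdx_peptides(data.frame(id = "a",
                                 sequence = paste(rep("A", 50),
                                                  collapse = ""),
                                 start = 1L, end = 50L, charge = 1L))
  expect_equal(sequence_coverage(one, 100), 50)
  two <- hdx_peptides(data.frame(
    id = c("a", "b"),
    sequence = c(paste(rep("A", 60), collapse = ""),
                 paste(rep("A", 40), collapse = "")),
    start = c(1L, 41L), end = c(60L, 80L), charge = 1L))
  expect_equal(sequence_coverage(two, 100), 80)
  expect_error(sequence_coverage(one, 40), "outside")
})
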