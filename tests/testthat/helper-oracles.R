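# shared fixtures and independent oracles used across test files

# a small protein with hand-set kinetics: 12 residues, one proline,
# two regions; construct numbering starts at 1 unless offset
tiny_protein <- function(log10P = rep(0, 12), k_int = rep(0.1, 12),
                         first_index = 1L) {
  hdx_protein("GASTLKVEDRIW", first_index = first_index,
              regions = data.frame(
                name = c("A", "B"),
                start = c(first_index, first_index + 6L),
                end = c(first_index + 5L, first_index + 11L)),
              log10_protection = log10P, k_int = k_int)
}

tiny_peptides <- function() {
  hdx_peptides(data.frame(
    id = c("p1", "p2"),
    sequence = c("GASTLKV", "KVEDRIW"),
    start = c(1L, 6L), end = c(7L, 12L), charge = c(2L, 1L)))
}

# brute-force step-up BH: literal definition, independent of p.adjust
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted value of the i-th smallest: min over j >= i of p(j)*m/j
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# brute-force residue consolidation: literal per-residue loop
brute_consolidate <- function(values, peptides, first_index, seq_length,
                              weight_fun = function(n) 1 / n) {
  out <- rep(NA_real_, seq_length)
  for (r in first_index:(first_index + seq_length - 1L)) {
    num <- den <- 0
    for (j in seq_len(nrow(peptides))) {
      if (is.na(values[peptides$id[j]])) next
      ex <- exchangeable_residues(peptides$start[j], peptides$end[j],
                                  peptides$sequence[j])
      if (r %in% ex) {
        w <- weight_fun(exchangeable_residue_count(peptides$sequence[j]))
        num <- num + w * values[peptides$id[j]]
        den <- den + w
      }
    }
    if (den > 0) out[r - first_index + 1L] <- num / den
  }
  out
}

# random peptide table over a random sequence, for property tests
random_peptide_table <- function(n_pep, seq_len = 40L) {
  aa <- c("A", "G", "S", "T", "L", "P")
  s <- paste(sample(aa, seq_len, replace = TRUE), collapse = "")
  starts <- sample(seq_len(seq_len - 6L), n_pep, replace = TRUE)
  ends <- pmin(starts + sample(4:12, n_pep, replace = TRUE), seq_len)
  keep <- vapply(seq_len(n_pep), function(j)
    exchangeable_residue_count(substring(s, starts[j], ends[j])) > 0,
    logical(1))
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(NULL)
  hdx_peptides(data.frame(
    id = paste0("r", seq_along(starts)),
    sequence = substring(s, starts, ends),
    start = starts, end = ends, charge = 1L))
}

# minimal perturbation object with a hand-set delta matrix, for unit
# tests of the screening layer
fake_perturbation <- function(delta, fdr = 0.05) {
  cells <- data.frame(peptide_id = colnames(delta),
                      timepoint_s = 10,
                      label = colnames(delta))
  structure(list(records = NULL, delta = delta, cells = cells,
                 compounds = rownames(delta), vehicle = "vehicle",
                 config = significance_config(fdr_threshold = fdr),
                 peptides = NULL),
            class = "hdx_perturbation")
}
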