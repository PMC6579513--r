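#' Protein model for exchange-kinetics simulation
#'
#' Bundles everything the forward simulator needs about one protein
#' construct: the amino-acid sequence in construct numbering, a table of
#' named structural regions (helices, sheet regions, loops), a per-residue
#' baseline protection factor (as log10 P) and a per-residue intrinsic
#' amide exchange rate \eqn{k_{int}} in 1/s. The observed exchange rate of
#' residue i is \eqn{k_{int,i} / P_i}: protection slows exchange, never
#' accelerates it, so \eqn{P_i \ge 1} (log10 P >= 0) is enforced.
#'
#' @param sequence single amino-acid string (one-letter codes).
#' @param first_index construct number of the first residue (e.g. 265 for a
#'   nuclear-receptor ligand-binding domain construct spanning 265-518).
#' @param regions data.frame with columns \code{name}, \code{start},
#'   \code{end} (construct numbering, inclusive). Regions may not extend
#'   beyond the construct.
#' @param log10_protection numeric vector, one value per residue, log10 of
#'   the baseline protection factor. Values below 0 are an error.
#' @param k_int numeric vector of intrinsic exchange rates (1/s), one per
#'   residue, strictly positive.
#' @return an object of class \code{hdx_protein}.
#' @seealso [synthetic_protein()] for a ready-made simulated construct.
#' @export
hdx_protein <- function(sequence, first_index = 1L, regions,
                        log10_protection, k_int) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence))
    stop("sequence must use the 20 standard one-letter amino-acid codes")
  first_index <- as.integer(first_index)
  last_index <- first_index + n - 1L
  regions <- as.data.frame(regions)
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end))
    stop("region start must not exceed region end")
  if (any(regions$start < first_index) || any(regions$end > last_index))
    stop("regions must lie within [", first_index, ", ", last_index, "]")
  if (anyDuplicated(regions$name))
    stop("region names must be unique")
  log10_protection <- as.numeric(log10_protection)
  k_int <- as.numeric(k_int)
  if (length(log10_protection) != n || length(k_int) != n)
    stop("log10_protection and k_int must have one value per residue")
  if (any(log10_protection < 0))
    stop("log10 protection factors must be >= 0 (P >= 1)")
  if (any(k_int <= 0)) stop("intrinsic rates must be > 0")
  structure(
    list(sequence = sequence, first_index = first_index,
         last_index = last_index, regions = regions,
         log10_protection = log10_protection, k_int = k_int),
    class = "hdx_protein")
}

#' @export
print.hdx_protein <- function(x, ...) {
  cat("HDX protein model\n")
  cat(sprintf("  residues %d-%d (%d aa), %d prolines\n", x$first_index,
              x$last_index, nchar(x$sequence),
              sum(strsplit(x$sequence, "")[[1]] == "P")))
  cat(sprintf("  %d regions: %s\n", nrow(x$regions),
              paste(x$regions$name, collapse = " ")))
  cat(sprintf("  log10 P in [%.2f, %.2f]; log10 k_int in [%.2f, %.2f]\n",
              min(x$log10_protection), max(x$log10_protection),
              min(log10(x$k_int)), max(log10(x$k_int))))
  invisible(x)
}

#' Default structural-region layout of the simulated LBD construct
#'
#' A plausible helix/sheet layout for a 254-residue nuclear-receptor
#' ligand-binding domain numbered 265-518: twelve helices H1-H12, a
#' beta-sheet region (BSR) between H5 and H6 forming part of the orthosteric
#' pocket, and inter-element loops. The layout is synthetic; only its
#' qualitative topology (H12 at the C-terminus, BSR near the pocket helices
#' H3/H5/H7) matters to the simulator.
#'
#' @param first_index construct number of the first residue.
#' @return data.frame with columns \code{name}, \code{start}, \code{end}.
#' @export
default_regions <- function(first_index = 265L) {
  off <- as.integer(first_index) - 265L
  r <- data.frame(
    name  = c("H1",  "H2",  "H3",  "H4",  "H5",  "BSR", "H6",  "H7",
              "H8",  "H9",  "H10", "H11", "H12"),
    start = c(269L, 300L, 318L, 344L, 360L, 376L, 394L, 405L,
              428L, 444L, 466L, 488L, 507L),
    end   = c(283L, 310L, 339L, 354L, 374L, 392L, 402L, 422L,
              438L, 460L, 486L, 500L, 516L))
  r$start <- r$start + off
  r$end <- r$end + off
  r
}

# per-region mean log10 protection used by the synthetic construct: the
# core exchanges slowly (well protected), the C-terminal H10-H12 exchanges
# fast (little protection, disordered activation helix in the apo state)
.default_region_log10P <- c(
  H1 = 1.6, H2 = 1.4, H3 = 1.9, H4 = 1.7, H5 = 2.2, BSR = 1.6, H6 = 2.0,
  H7 = 1.7, H8 = 2.3, H9 = 2.2, H10 = 0.5, H11 = 0.3, H12 = 0.2,
  loop = 0.9)

#' Simulate a protein construct with realistic exchange heterogeneity
#'
#' Generates a random 254-residue sequence (prolines placed explicitly so
#' that exchangeable-residue exclusion rules are exercised downstream),
#' assigns the [default_regions()] layout, draws per-residue baseline
#' log10 protection factors from region-specific normal distributions
#' (fast-exchanging C-terminal helices, slow core; truncated at 0 so P >= 1)
#' and samples log10 intrinsic rates uniformly on [-4, 2] (1/s). Absolute
#' intrinsic rates never enter the downstream statistics -- only relative
#' protection does -- so a sequence-dependent intrinsic-rate table is not
#' used.
#'
#' @param n_residues construct length.
#' @param first_index construct number of the first residue.
#' Intrinsic rates are drawn log-uniformly, but over a faster window for
#' the C-terminal helices H10-H12 (\code{fast_log10k_range}) than for the
#' rest of the construct: with their low baseline protection this
#' reproduces the observed phenotype of a C-terminal activation helix
#' that has largely exchanged within seconds in the apo state, so that
#' ligand stabilisation of H12 shows up at short exposure and is mostly
#' saturated again by 4 hr.
#'
#' @param proline_fraction fraction of positions set to proline (no
#'   exchangeable backbone amide hydrogen).
#' @param protection_sd within-region spread of log10 P.
#' @param log10k_range range of log10 intrinsic rate (1/s) for most
#'   residues.
#' @param fast_log10k_range range for residues in \code{fast_regions}.
#' @param fast_regions regions given the faster intrinsic window.
#' @param seed integer seed; the construct is fully determined by it.
#' @return an \code{hdx_protein}.
#' @export
synthetic_protein <- function(n_residues = 254L, first_index = 265L,
                              proline_fraction = 0.05,
                              protection_sd = 0.35,
                              log10k_range = c(-4, 2),
                              fast_log10k_range = c(-1.3, 2),
                              fast_regions = c("H10", "H11", "H12"),
                              seed = 1L) {
  set.seed(as.integer(seed))
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","Q","R","S","T",
          "V","W","Y")
  seq_chars <- sample(aa, n_residues, replace = TRUE)
  n_pro <- max(1L, round(proline_fraction * n_residues))
  # never a proline at position 1 so the construct always starts exchangeable
  pro_pos <- sample(2:n_residues, n_pro)
  seq_chars[pro_pos] <- "P"
  regions <- default_regions(first_index)
  region_of <- rep("loop", n_residues)
  idx <- first_index:(first_index + n_residues - 1L)
  for (j in seq_len(nrow(regions))) {
    sel <- idx >= regions$start[j] & idx <= regions$end[j]
    region_of[sel] <- regions$name[j]
  }
  mu <- .default_region_log10P[region_of]
  log10P <- pmax(0, stats::rnorm(n_residues, mean = mu, sd = protection_sd))
  lo <- ifelse(region_of %in% fast_regions, fast_log10k_range[1],
               log10k_range[1])
  hi <- ifelse(region_of %in% fast_regions, fast_log10k_range[2],
               log10k_range[2])
  k_int <- 10^stats::runif(n_residues, lo, hi)
  hdx_protein(paste(seq_chars, collapse = ""), first_index, regions,
              log10P, k_int)
}

#' Residues belonging to a named region
#'
#' @param protein an \code{hdx_protein}.
#' @param region region name present in \code{protein$regions}.
#' @return integer vector of residue numbers (construct numbering).
#' @export
region_residues <- function(protein, region) {
  r <- protein$regions[protein$regions$name == region, ]
  if (nrow(r) == 0L) stop("unknown region: ", region)
  seq.int(r$start, r$end)
}
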